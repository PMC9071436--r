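#' Write a trajectory as XYZ
#'
#' One block per frame: bead count, a comment line carrying the time and the
#' soft-segment annotation, then one `elem x y z` line per bead. Beads inside
#' the TopoII segment get element tag "T", the rest "C". Coordinates are
#' printed with enough digits for a lossless round trip at printed precision.
#'
#' @param traj a `kr_trajectory` (or list with `frames`, `times`,
#'   `seg_start`)
#' @param path output file
#' @param l_T segment length used for the element tags (default: from the
#'   trajectory's `topo`, else 0)
#' @export
write_xyz <- function(traj, path, l_T = if (!is.null(traj$topo)) traj$topo$l_T else 0L) {
  nf <- dim(traj$frames)[3]
  N <- dim(traj$frames)[1]
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(nf)) {
    seg <- if (!is.null(traj$seg_start)) traj$seg_start[f] else 1L
    elem <- rep("C", N)
    if (l_T > 0) elem[((seg - 1 + 0:(l_T - 1)) %% N) + 1] <- "T"
    writeLines(as.character(N), con)
    writeLines(sprintf("t=%.10g seg_start=%d l_T=%d", traj$times[f], seg, l_T), con)
    m <- traj$frames[, , f]
    writeLines(sprintf("%s %.10g %.10g %.10g", elem, m[, 1], m[, 2], m[, 3]), con)
  }
  invisible(path)
}

#' Read an XYZ trajectory
#'
#' @param path file written by [write_xyz()] (or any plain XYZ with a
#'   `t=... seg_start=... l_T=...` comment line)
#' @return list(frames, times, seg_start, l_T, elements)
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) stop("empty trajectory file: ", path)
  frames <- list(); times <- numeric(0); segs <- integer(0); lT <- 0L
  elements <- NULL
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    N <- suppressWarnings(as.integer(lines[i]))
    if (is.na(N) || N < 1)
      stop("malformed XYZ header at line ", i, ": '", lines[i], "'")
    if (i + 1L + N > length(lines))
      stop("truncated XYZ frame starting at line ", i)
    cm <- lines[i + 1L]
    t <- grab_num(cm, "t"); sg <- grab_num(cm, "seg_start")
    ltv <- grab_num(cm, "l_T")
    body <- lines[(i + 2L):(i + 1L + N)]
    parts <- strsplit(trimws(body), "[[:space:]]+")
    if (any(lengths(parts) != 4))
      stop("malformed XYZ atom line near line ", i + 2L)
    elements <- vapply(parts, `[`, "", 1)
    m <- matrix(as.numeric(unlist(lapply(parts, `[`, 2:4))), ncol = 3,
                byrow = TRUE)
    if (anyNA(m)) stop("non-numeric coordinate near line ", i + 2L)
    frames[[length(frames) + 1L]] <- m
    times <- c(times, if (is.na(t)) length(frames) - 1 else t)
    segs <- c(segs, if (is.na(sg)) 1L else as.integer(sg))
    if (!is.na(ltv)) lT <- as.integer(ltv)
    i <- i + 2L + N
  }
  if (!length(frames)) stop("empty trajectory file: ", path)
  N <- nrow(frames[[1]])
  if (any(vapply(frames, nrow, 1L) != N))
    stop("inconsistent bead counts across frames in ", path)
  arr <- array(unlist(frames), dim = c(N, 3, length(frames)))
  list(frames = arr, times = times, seg_start = segs, l_T = lT,
       elements = elements)
}

grab_num <- function(s, key) {
  m <- regmatches(s, regexec(paste0(key, "=([-0-9.eE+]+)"), s))[[1]]
  if (length(m) < 2) NA_real_ else as.numeric(m[2])
}

#' Write a LAMMPS-dump-style trajectory
#'
#' Text dialect with per-frame headers `ITEM: TIMESTEP`, `ITEM: NUMBER OF
#' ATOMS`, `ITEM: BOX BOUNDS` and `ITEM: ATOMS id type x y z`; type 2 marks
#' beads of the soft segment, type 1 the rest. Atom ids are 1-based; readers
#' must re-order rows by id.
#'
#' @inheritParams write_xyz
#' @export
write_dump <- function(traj, path, l_T = if (!is.null(traj$topo)) traj$topo$l_T else 0L) {
  nf <- dim(traj$frames)[3]
  N <- dim(traj$frames)[1]
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(nf)) {
    seg <- if (!is.null(traj$seg_start)) traj$seg_start[f] else 1L
    type <- rep(1L, N)
    if (l_T > 0) type[((seg - 1 + 0:(l_T - 1)) %% N) + 1] <- 2L
    m <- traj$frames[, , f]
    lim <- max(abs(m)) + 1
    writeLines(c("ITEM: TIMESTEP", sprintf("%.10g", traj$times[f]),
                 "ITEM: NUMBER OF ATOMS", as.character(N),
                 "ITEM: BOX BOUNDS ff ff ff",
                 rep(sprintf("%.10g %.10g", -lim, lim), 3),
                 "ITEM: ATOMS id type x y z"), con)
    writeLines(sprintf("%d %d %.10g %.10g %.10g", seq_len(N), type,
                       m[, 1], m[, 2], m[, 3]), con)
  }
  invisible(path)
}

#' Read a LAMMPS-dump-style trajectory
#'
#' @param path file in the dialect of [write_dump()]
#' @return list(frames, times, seg_start, l_T, types); atoms re-ordered by id
#' @export
read_dump <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) stop("empty trajectory file: ", path)
  frames <- list(); times <- numeric(0); segs <- integer(0); lT <- 0L
  types <- NULL
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    if (!startsWith(lines[i], "ITEM: TIMESTEP"))
      stop("expected 'ITEM: TIMESTEP' at line ", i)
    t <- as.numeric(lines[i + 1L])
    if (!startsWith(lines[i + 2L], "ITEM: NUMBER OF ATOMS"))
      stop("expected 'ITEM: NUMBER OF ATOMS' at line ", i + 2L)
    N <- as.integer(lines[i + 3L])
    if (is.na(N) || N < 1) stop("bad atom count at line ", i + 3L)
    j <- i + 4L
    if (!startsWith(lines[j], "ITEM: BOX BOUNDS"))
      stop("expected 'ITEM: BOX BOUNDS' at line ", j)
    j <- j + 4L
    if (!startsWith(lines[j], "ITEM: ATOMS"))
      stop("expected 'ITEM: ATOMS' at line ", j)
    cols <- strsplit(sub("ITEM: ATOMS ?", "", lines[j]), "[[:space:]]+")[[1]]
    need <- c("id", "type", "x", "y", "z")
    if (!all(need %in% cols))
      stop("dump header at line ", j, " lacks columns: ",
           paste(setdiff(need, cols), collapse = ", "))
    body <- lines[(j + 1L):(j + N)]
    parts <- strsplit(trimws(body), "[[:space:]]+")
    if (any(lengths(parts) != length(cols)))
      stop("malformed atom line near line ", j + 1L)
    tab <- matrix(as.numeric(unlist(parts)), ncol = length(cols), byrow = TRUE)
    colnames(tab) <- cols
    if (anyNA(tab)) stop("non-numeric field near line ", j + 1L)
    ord <- order(tab[, "id"])
    tab <- tab[ord, , drop = FALSE]
    frames[[length(frames) + 1L]] <- tab[, c("x", "y", "z")]
    types <- as.integer(tab[, "type"])
    seg_beads <- which(types == 2L)
    segs <- c(segs, if (length(seg_beads)) seg_start_from_beads(seg_beads, N) else 1L)
    if (length(seg_beads)) lT <- length(seg_beads)
    times <- c(times, t)
    i <- j + N + 1L
  }
  N <- nrow(frames[[1]])
  if (any(vapply(frames, nrow, 1L) != N))
    stop("inconsistent bead counts across frames in ", path)
  arr <- array(unlist(frames), dim = c(N, 3, length(frames)))
  list(frames = arr, times = times, seg_start = segs, l_T = lT, types = types)
}

# recover the cyclic start of a contiguous bead set
seg_start_from_beads <- function(beads, N) {
  inset <- logical(N); inset[beads] <- TRUE
  starts <- which(inset & !inset[c(N, seq_len(N - 1))])
  if (length(starts)) starts[1] else beads[1]
}

#' Read / write key = value configuration files
#'
#' The declarative run-configuration dialect: one `key = value` pair per
#' line, `#` comments, numbers parsed as numerics, everything else kept as
#' strings.
#' @param path file path
#' @return named list
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("malformed config line: '", ln, "'")
    key <- trimws(kv[1]); val <- trimws(kv[2])
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}

#' @rdname read_config
#' @param config named list to write
#' @export
write_config <- function(config, path) {
  writeLines(sprintf("%s = %s", names(config),
                     vapply(config, function(v) format(v, digits = 15), "")),
             path)
  invisible(path)
}

#' Write a run manifest
#'
#' Records the full configuration, seed and package version, sufficient to
#' reproduce the run bit for bit.
#' @param path output JSON path
#' @param config named list of settings
#' @param seed integer seed
#' @export
write_manifest <- function(path, config, seed) {
  jsonlite::write_json(
    list(package = "knotrelax",
         version = as.character(utils::packageVersion("knotrelax")),
         seed = seed, config = config,
         r_version = R.version.string),
    path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
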