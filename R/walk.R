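#' Knot-space disk layout
#'
#' Builds the idealised 2D knot spaces: a chain of slightly overlapping
#' disks, one per knot type, whose areas stand for the number of available
#' configurations (the unknot disk is the largest). The default is the
#' collinear chain unknot - 3_1 - 5_1 with radius ratio 4:2:1 and centre
#' spacings giving a 5% (of the smaller radius) overlap between adjacent
#' disks.
#'
#' @param radii named numeric vector of disk radii, ordered along the
#'   simplification path ending at the unknot first element; exactly one
#'   entry must be named "unknot"
#' @param overlap lens depth between adjacent disks as a fraction of the
#'   smaller radius
#' @param annulus_width rim-annulus width (model iii) as a fraction of radius
#' @param strip_width strip width (model iv) as a fraction of radius
#' @return object of class `knot_layout`: data frame of disks plus settings
#' @export
#' @examples
#' lay <- build_layout()
#' lay$disks
build_layout <- function(radii = c(unknot = 4, "3_1" = 2, "5_1" = 1),
                         overlap = 0.05, annulus_width = 0.1,
                         strip_width = 0.1) {
  stopifnot(length(radii) >= 2, all(radii > 0), overlap > 0, overlap < 1)
  if (sum(names(radii) == "unknot") != 1)
    stop("exactly one disk must be labelled 'unknot'")
  n <- length(radii)
  cx <- numeric(n)
  for (k in 2:n)
    cx[k] <- cx[k - 1] + radii[k - 1] + radii[k] -
      overlap * min(radii[k - 1], radii[k])
  disks <- data.frame(label = names(radii), cx = cx, cy = 0, r = unname(radii),
                      stringsAsFactors = FALSE)
  # adjacency check: consecutive disks overlap, non-adjacent ones are disjoint
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    d <- abs(disks$cx[i] - disks$cx[j])
    if (j == i + 1) {
      if (d >= disks$r[i] + disks$r[j])
        stop("adjacent disks ", i, " and ", j, " do not overlap")
    } else if (d <= disks$r[i] + disks$r[j]) {
      stop("non-adjacent disks ", i, " and ", j, " overlap")
    }
  }
  structure(list(disks = disks, overlap = overlap,
                 annulus_width = annulus_width, strip_width = strip_width),
            class = "knot_layout")
}

# label = disk whose centre-normalised distance |x - c|/r is smallest among
# the disks containing the point; NA if outside the union
layout_label <- function(layout, x, y) {
  d <- layout$disks
  n <- nrow(d)
  best <- rep(NA_integer_, length(x))
  bestv <- rep(Inf, length(x))
  for (k in seq_len(n)) {
    v <- sqrt((x - d$cx[k])^2 + (y - d$cy[k])^2) / d$r[k]
    upd <- v <= 1 & v < bestv
    best[upd] <- k
    bestv[upd] <- v[upd]
  }
  best
}

# vectorised single step shared by step_walker() and run_ensemble()
walk_step_n <- function(px, py, disk, layout, dt, D_walk, jump_rate, model) {
  d <- layout$disks
  n <- length(px)
  sdx <- sqrt(2 * D_walk * dt)
  qx <- px + rnorm(n, 0, sdx)
  qy <- py + rnorm(n, 0, sdx)
  lab <- layout_label(layout, qx, qy)
  out <- is.na(lab)
  if (any(out)) {
    # radial reflection at the current disk's rim (re-entry through an
    # overlap region is already handled: those points are inside the union)
    cx <- d$cx[disk[out]]; cy <- d$cy[disk[out]]; r <- d$r[disk[out]]
    vx <- qx[out] - cx; vy <- qy[out] - cy
    rho <- sqrt(vx^2 + vy^2)
    fac <- (2 * r - rho) / rho
    rx <- cx + vx * fac; ry <- cy + vy * fac
    rl <- layout_label(layout, rx, ry)
    ok <- !is.na(rl)
    idx <- which(out)
    qx[idx[ok]] <- rx[ok]; qy[idx[ok]] <- ry[ok]
    qx[idx[!ok]] <- px[idx[!ok]]; qy[idx[!ok]] <- py[idx[!ok]]  # reject
    lab <- layout_label(layout, qx, qy)
  }
  disk <- lab
  if (model != "i" && jump_rate > 0) {
    jump <- runif(n) < jump_rate * dt
    if (any(jump)) {
      for (k in unique(disk[jump])) {
        sel <- which(jump & disk == k)
        tp <- sample_kernel(layout, k, length(sel), model)
        qx[sel] <- tp$x; qy[sel] <- tp$y
      }
      disk <- layout_label(layout, qx, qy)
    }
  }
  list(x = qx, y = qy, disk = disk)
}

# teleport kernels: ii uniform over the disk, iii uniform over the rim
# annulus, iv uniform over the vertical strip facing the neighbour of lower
# knot complexity (for the unknot disk, which has no such neighbour, iv and
# iii fall back to a uniform jump)
sample_kernel <- function(layout, k, n, model) {
  d <- layout$disks
  r <- d$r[k]; cx <- d$cx[k]; cy <- d$cy[k]
  if (model == "ii" || (k == 1 && model == "iv")) {
    rad <- r * sqrt(runif(n))
    th <- runif(n, 0, 2 * pi)
    return(list(x = cx + rad * cos(th), y = cy + rad * sin(th)))
  }
  if (model == "iii") {
    r0 <- r * (1 - layout$annulus_width)
    rad <- sqrt(runif(n, r0^2, r^2))
    th <- runif(n, 0, 2 * pi)
    return(list(x = cx + rad * cos(th), y = cy + rad * sin(th)))
  }
  # model iv: strip of width strip_width * r at the disk edge nearest the
  # previous (lower-complexity) disk in the chain, i.e. toward smaller x
  w <- layout$strip_width * r
  x0 <- cx - r; x1 <- cx - r + w
  xs <- ys <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    tx <- runif(length(need), x0, x1)
    ty <- runif(length(need), cy - r, cy + r)
    keep <- (tx - cx)^2 + (ty - cy)^2 < r^2
    xs[need[keep]] <- tx[keep]; ys[need[keep]] <- ty[keep]
    need <- need[!keep]
  }
  list(x = xs, y = ys)
}

#' Walker state
#'
#' @param position length-2 numeric (x, y)
#' @param layout a [build_layout()]
#' @param model "i" (diffusion only), "ii" (uniform jumps), "iii" (annulus
#'   jumps) or "iv" (strip jumps)
#' @param D_walk diffusion coefficient
#' @param jump_rate teleport rate (events per time unit)
#' @return object of class `walker_state`
#' @export
walker_state <- function(position, layout, model = c("i", "ii", "iii", "iv"),
                         D_walk = 0.5, jump_rate = 300) {
  model <- match.arg(model)
  lab <- layout_label(layout, position[1], position[2])
  if (is.na(lab)) stop("walker position lies outside the union of disks")
  structure(list(position = as.numeric(position), disk = lab,
                 label = layout$disks$label[lab], model = model,
                 D_walk = D_walk, jump_rate = jump_rate),
            class = "walker_state")
}

#' Advance a walker one time step
#'
#' Gaussian displacement with per-axis variance 2 D dt, reflected radially at
#' the current disk's rim except where the move enters an adjacent disk
#' (which re-labels the walker); for models ii-iv a teleport fires with
#' probability `jump_rate * dt` this step. Uses R's RNG.
#'
#' @param w a [walker_state()]
#' @param layout a [build_layout()]
#' @param dt time step
#' @return the updated `walker_state`
#' @export
step_walker <- function(w, layout, dt) {
  s <- walk_step_n(w$position[1], w$position[2], w$disk, layout, dt,
                   w$D_walk, w$jump_rate, w$model)
  w$position <- c(s$x, s$y)
  w$disk <- s$disk
  w$label <- layout$disks$label[s$disk]
  w
}

#' Ensemble of knot-space walkers
#'
#' Starts `n_walkers` at the centre of `start_label`'s disk (the 5_1 space by
#' default) and records the fraction still outside the unknot disk, the
#' knotting probability P_K(t), along with its early-time exponential decay
#' time.
#'
#' @param layout a [build_layout()]
#' @param model "i".."iv"
#' @param n_walkers ensemble size (default 1000)
#' @param horizon total simulated time (time units)
#' @param dt time step (default 1e-3)
#' @param D_walk diffusion coefficient (default 0.5)
#' @param jump_rate teleports per time unit (default 300)
#' @param start_label initial disk
#' @param record_every record P_K every this many steps
#' @param record_walker index of one walker whose full trajectory
#'   (t, x, y, label) is kept, or 0 for none
#' @param seed RNG seed (deterministic given the seed)
#' @return list(curve (`relaxation_curve` data frame), tau, occupancy:
#'   long-run fraction of time-steps x walkers per disk over the last half
#'   of the run, and `path` when a walker is recorded)
#' @export
run_ensemble <- function(layout, model = c("i", "ii", "iii", "iv"),
                         n_walkers = 1000, horizon = 30, dt = 1e-3,
                         D_walk = 0.5, jump_rate = 300,
                         start_label = "5_1", record_every = 50L,
                         record_walker = 0L, seed = 1L) {
  model <- match.arg(model)
  d <- layout$disks
  k0 <- match(start_label, d$label)
  if (is.na(k0)) stop("unknown start label ", start_label)
  unk <- match("unknot", d$label)
  set.seed(seed)
  n_steps <- ceiling(horizon / dt)
  px <- rep(d$cx[k0], n_walkers); py <- rep(d$cy[k0], n_walkers)
  disk <- rep(k0, n_walkers)
  rec <- seq(0, n_steps, by = record_every)
  pk <- numeric(length(rec)); pk[1] <- mean(disk != unk)
  occ_counts <- numeric(nrow(d))
  occ_n <- 0
  ri <- 2
  keep_path <- record_walker >= 1 && record_walker <= n_walkers
  if (keep_path)
    path <- data.frame(t = (0:n_steps) * dt, x = NA_real_, y = NA_real_,
                       label = NA_character_)
  if (keep_path) {
    path$x[1] <- px[record_walker]; path$y[1] <- py[record_walker]
    path$label[1] <- d$label[disk[record_walker]]
  }
  for (s in seq_len(n_steps)) {
    st <- walk_step_n(px, py, disk, layout, dt, D_walk, jump_rate, model)
    px <- st$x; py <- st$y; disk <- st$disk
    if (s > n_steps / 2) {
      tb <- tabulate(disk, nrow(d))
      occ_counts <- occ_counts + tb
      occ_n <- occ_n + n_walkers
    }
    if (keep_path) {
      path$x[s + 1] <- px[record_walker]; path$y[s + 1] <- py[record_walker]
      path$label[s + 1] <- d$label[disk[record_walker]]
    }
    if (ri <= length(rec) && s == rec[ri]) {
      pk[ri] <- mean(disk != unk)
      ri <- ri + 1
    }
  }
  curve <- structure(data.frame(time = rec * dt, P_K = pk,
                                sem = sqrt(pmax(pk * (1 - pk), 0) / n_walkers)),
                     class = c("relaxation_curve", "data.frame"))
  out <- list(curve = curve, tau = fit_decay(curve)$tau,
              occupancy = setNames(occ_counts / max(occ_n, 1), d$label))
  if (keep_path) out$path <- path
  out
}
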