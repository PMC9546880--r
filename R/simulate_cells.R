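# Single-cell imaging fixtures: spatial point patterns with bimodal DAPI/EdU
# marker intensities, correlated-random-walk lineage tracks with Poisson
# divisions, and module-coupled well-level phenotypes.

#' Generate a single-cell table with a chosen spatial pattern
#'
#' Patterns: `csr` places n independent uniform points (complete spatial
#' randomness); `thomas` scatters n offspring around uniform parent centres
#' with isotropic Gaussian dispersion (the tight-cluster phenotype); `grid`
#' places a regular lattice (the evenly-dispersed phenotype). Total nuclear
#' DAPI is a two-component mixture at means mu and 2*mu (G1/G2M), EdU a
#' two-component log-normal mixture.
#'
#' @param pattern one of `"csr"`, `"thomas"`, `"grid"`.
#' @param n number of cells (>= 1).
#' @param field `c(width, height)` in pixels.
#' @param params list of pattern/marker parameters: `n_parents`, `sigma`
#'   (thomas); `dapi_mu`, `dapi_cv`, `g2m_frac`; `edu_mu_neg`, `edu_mu_pos`,
#'   `edu_sdlog`, `edu_pos_frac`; `krt5_meanlog`, `krt5_sdlog`;
#'   `multinucleated_frac`; `well`, `field_id`.
#' @param seed integer seed.
#' @return A data.frame with columns `well`, `field`, `cell_id`, `x`, `y`,
#'   `dapi_total`, `edu`, `krt5`, `n_nuclei` plus generator-truth columns
#'   `true_phase` and `true_edu_pos`.
#' @export
generate_cells <- function(pattern = c("csr", "thomas", "grid"), n,
                           field = c(1000, 1000), params = list(), seed = 1L) {
  pattern <- match.arg(pattern)
  if (n < 1) stop("`n` must be >= 1")
  if (any(field <= 0)) stop("`field` must be positive")
  p <- modifyList(list(n_parents = 10, sigma = 30,
                       dapi_mu = 1000, dapi_cv = 0.1, g2m_frac = 0.5,
                       edu_mu_neg = 100, edu_mu_pos = 1000, edu_sdlog = 0.3,
                       edu_pos_frac = 0.3,
                       krt5_meanlog = log(200), krt5_sdlog = 0.3,
                       multinucleated_frac = 0.02,
                       well = "A1", field_id = 1L), params)
  set.seed(derive_seed(seed, paste0("cells_", pattern)))
  w <- field[1]; h <- field[2]
  if (pattern == "csr") {
    x <- runif(n, 0, w); y <- runif(n, 0, h)
  } else if (pattern == "thomas") {
    np <- max(1L, as.integer(p$n_parents))
    px <- runif(np, 0, w); py <- runif(np, 0, h)
    par_of <- sample.int(np, n, replace = TRUE)
    x <- px[par_of] + rnorm(n, 0, p$sigma)
    y <- py[par_of] + rnorm(n, 0, p$sigma)
    x <- pmin(pmax(x, 0), w); y <- pmin(pmax(y, 0), h)
  } else {
    nx <- round(sqrt(n * w / h))
    ny <- if (nx > 0) n / nx else 0
    if (nx < 1 || ny != round(ny))
      stop("grid pattern requires n to factor as nx * ny matching the aspect ratio")
    s <- w / nx
    if (ny * s > h + 1e-9)
      stop("n exceeds the field capacity for a square-spaced grid")
    gx <- (seq_len(nx) - 0.5) * s
    gy <- (seq_len(ny) - 0.5) * (h / ny)
    g <- expand.grid(x = gx, y = gy)
    x <- g$x; y <- g$y
  }
  g2m <- rbinom(n, 1, p$g2m_frac) == 1
  dapi_mean <- ifelse(g2m, 2 * p$dapi_mu, p$dapi_mu)
  dapi <- pmax(rnorm(n, dapi_mean, p$dapi_cv * dapi_mean), 1e-6)
  edu_pos <- rbinom(n, 1, p$edu_pos_frac) == 1
  edu <- rlnorm(n, log(ifelse(edu_pos, p$edu_mu_pos, p$edu_mu_neg)), p$edu_sdlog)
  krt5 <- rlnorm(n, p$krt5_meanlog, p$krt5_sdlog)
  n_nuclei <- 1L + rbinom(n, 1, p$multinucleated_frac)
  data.frame(well = p$well, field = p$field_id, cell_id = seq_len(n),
             x = x, y = y, dapi_total = dapi, edu = edu, krt5 = krt5,
             n_nuclei = n_nuclei,
             true_phase = ifelse(g2m, "G2M", "G1"), true_edu_pos = edu_pos,
             stringsAsFactors = FALSE)
}

#' Generate lineage tracks as correlated random walks with divisions
#'
#' Founder cells perform a correlated random walk (per-axis step
#' `v_t = persistence * v_{t-1} + sqrt(1 - persistence^2) * N(0, speed^2)`, so
#' the stationary per-axis step sd equals `speed`). Divisions are Poisson
#' events with the given hourly rate; a dividing track ends and two daughters
#' start at its position on the division frame.
#'
#' @param n_lineages number of founder cells.
#' @param motility list with `speed` (px/frame per-axis step sd, >= 0) and
#'   `persistence` in `[0, 1)`.
#' @param division_rate divisions per hour per cell (>= 0).
#' @param horizon hours of imaging (> 0).
#' @param dt frame interval in hours.
#' @param field `c(width, height)` for founder placement.
#' @param seed integer seed.
#' @return List with `tracks` (long data.frame: `track_id`, `parent_id`,
#'   `frame`, `x`, `y`) and `mitoses` (`frame`, `parent`, `daughter1`,
#'   `daughter2`).
#' @export
generate_tracks <- function(n_lineages, motility = list(speed = 5, persistence = 0.5),
                            division_rate = 1 / 30, horizon = 48, dt = 0.5,
                            field = c(1000, 1000), seed = 1L) {
  if (horizon <= 0) stop("`horizon` must be > 0")
  if (motility$speed < 0) stop("`speed` must be >= 0")
  if (division_rate < 0) stop("`division_rate` must be >= 0")
  set.seed(derive_seed(seed, "tracks"))
  n_frames <- as.integer(round(horizon / dt))
  p_div <- 1 - exp(-division_rate * dt)
  speed <- motility$speed
  rho <- motility$persistence
  next_id <- 0L
  rows <- list(); mit <- list()
  # queue of tracks to simulate: (id, parent, start frame, x, y, vx, vy)
  queue <- lapply(seq_len(n_lineages), function(i) {
    next_id <<- next_id + 1L
    list(id = next_id, parent = NA_integer_, frame = 0L,
         x = runif(1, 0, field[1]), y = runif(1, 0, field[2]),
         vx = rnorm(1, 0, speed), vy = rnorm(1, 0, speed))
  })
  while (length(queue)) {
    tr <- queue[[1]]; queue <- queue[-1]
    fr <- tr$frame; x <- tr$x; y <- tr$y; vx <- tr$vx; vy <- tr$vy
    xs <- x; ys <- y; frames <- fr
    divided <- FALSE
    while (fr < n_frames) {
      fr <- fr + 1L
      vx <- rho * vx + sqrt(1 - rho^2) * rnorm(1, 0, speed)
      vy <- rho * vy + sqrt(1 - rho^2) * rnorm(1, 0, speed)
      x <- x + vx; y <- y + vy
      xs <- c(xs, x); ys <- c(ys, y); frames <- c(frames, fr)
      if (fr < n_frames && runif(1) < p_div) { divided <- TRUE; break }
    }
    rows[[length(rows) + 1L]] <-
      data.frame(track_id = tr$id, parent_id = tr$parent, frame = frames,
                 x = xs, y = ys)
    if (divided) {
      d1 <- next_id + 1L; d2 <- next_id + 2L; next_id <- next_id + 2L
      mit[[length(mit) + 1L]] <-
        data.frame(frame = fr, parent = tr$id, daughter1 = d1, daughter2 = d2)
      for (d in c(d1, d2))
        queue[[length(queue) + 1L]] <-
          list(id = d, parent = tr$id, frame = fr, x = x, y = y,
               vx = rnorm(1, 0, speed), vy = rnorm(1, 0, speed))
    }
  }
  list(tracks = do.call(rbind, rows),
       mitoses = if (length(mit)) do.call(rbind, mit) else
         data.frame(frame = integer(), parent = integer(),
                    daughter1 = integer(), daughter2 = integer()),
       dt = dt, n_frames = n_frames)
}

#' Generate module-coupled well-level phenotypes
#'
#' Well-level phenotype values are linear combinations of the true (planted)
#' module scores at that well's condition plus Gaussian noise. True module
#' scores are the planted effect profiles standardized across the 24H/48H
#' conditions, putting coupling slopes on the same scale as the module scores
#' the pipeline estimates from scaled data.
#'
#' @param truth the `truth` element returned by [generate_multiomic()].
#' @param design sample-metadata table.
#' @param coupling named list: phenotype name -> named numeric vector of
#'   slopes over modules (`M1`, `M2`, ...).
#' @param noise_sd Gaussian well noise sd.
#' @param times time points at which phenotypes are scored.
#' @param seed integer seed.
#' @return A data.frame: `ligand`, `time`, `replicate`, then one column per
#'   phenotype.
#' @export
generate_phenotypes <- function(truth, design, coupling, noise_sd = 0.5,
                                times = c(24, 48), seed = 1L) {
  if (is.null(truth$profiles)) stop("truth does not carry module profiles")
  set.seed(derive_seed(seed, "phenotypes"))
  wells <- design[design$time %in% times & design$ligand != "CTRL",
                  c("ligand", "time", "replicate")]
  keys <- condition_key(wells$ligand, wells$time)
  use_keys <- unique(keys)
  prof <- truth$profiles[, use_keys, drop = FALSE]
  zprof <- t(apply(prof, 1, function(r) as.numeric(scale(r))))
  dimnames(zprof) <- dimnames(prof)
  out <- wells
  for (ph in names(coupling)) {
    beta <- coupling[[ph]]
    sc <- colSums(zprof[names(beta), , drop = FALSE] * beta)
    out[[ph]] <- sc[keys] + rnorm(nrow(wells), 0, noise_sd)
  }
  rownames(out) <- NULL
  out
}
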