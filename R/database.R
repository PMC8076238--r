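#' Optical-property grid specification
#'
#' The reflectance lookup grid spans mu_a from 0.001 to 1.00 mm^-1 in steps of
#' 0.001 and mu_s' from 0.10 to 3.00 mm^-1 in steps of 0.10 (1000 x 30 nodes
#' when unthinned).  `mu_a_thin` keeps every k-th absorption node for
#' desk-scale builds; the default thinning of 10 yields a 100 x 30 grid.
#'
#' @param mu_a_range,mu_a_step absorption range and step, mm^-1.
#' @param mu_sp_range,mu_sp_step reduced-scattering range and step, mm^-1.
#' @param mu_a_thin keep roughly `1/mu_a_thin` of the absorption nodes
#'   (1 = full grid).
#' @param mu_sp_thin keep every `mu_sp_thin`-th scattering node.
#' @param thin_scheme how thinned absorption nodes are selected from the
#'   full grid: `"low_dense"` (default) keeps every node up to 0.03 mm^-1
#'   and log-spaces the rest -- tissue water bands live at low absorption,
#'   where the inverse map needs the most support; `"uniform"` keeps every
#'   `mu_a_thin`-th node.
#' @return An object of class `grid_spec` with node vectors `mu_a` and
#'   `mu_sp`.
#' @export
grid_spec <- function(mu_a_range = c(0.001, 1.00), mu_a_step = 0.001,
                      mu_sp_range = c(0.10, 3.00), mu_sp_step = 0.10,
                      mu_a_thin = 10, mu_sp_thin = 1,
                      thin_scheme = c("low_dense", "uniform")) {
  thin_scheme <- match.arg(thin_scheme)
  stopifnot(mu_a_step > 0, mu_sp_step > 0,
            mu_a_range[1] > 0, mu_a_range[2] > mu_a_range[1],
            mu_sp_range[1] > 0, mu_sp_range[2] > mu_sp_range[1],
            mu_a_thin >= 1, mu_sp_thin >= 1)
  mu_a <- seq(mu_a_range[1], mu_a_range[2], by = mu_a_step)
  mu_sp <- seq(mu_sp_range[1], mu_sp_range[2], by = mu_sp_step)
  n_keep <- ceiling(length(mu_a) / mu_a_thin)
  if (mu_a_thin == 1) {
    mu_a_sel <- mu_a
  } else if (thin_scheme == "uniform") {
    mu_a_sel <- mu_a[seq(1, length(mu_a), by = mu_a_thin)]
  } else {
    low <- mu_a[mu_a <= 0.03 + 1e-12]
    n_hi <- max(2, n_keep - length(low))
    hi_targets <- 10^seq(log10(0.03), log10(mu_a_range[2]),
                         length.out = n_hi + 1)[-1]
    hi <- mu_a[pmin(length(mu_a),
                    pmax(1, round((hi_targets - mu_a_range[1]) / mu_a_step) + 1))]
    mu_a_sel <- sort(unique(c(low, hi)))
  }
  structure(list(mu_a_full = mu_a, mu_sp_full = mu_sp,
                 mu_a = mu_a_sel,
                 mu_sp = mu_sp[seq(1, length(mu_sp), by = mu_sp_thin)],
                 mu_a_thin = mu_a_thin, mu_sp_thin = mu_sp_thin,
                 thin_scheme = thin_scheme),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat("Optical-property grid:", length(x$mu_a), "mu_a nodes x",
      length(x$mu_sp), "mu_s' nodes =", length(x$mu_a) * length(x$mu_sp),
      "rows\n  (full grid:", length(x$mu_a_full), "x", length(x$mu_sp_full),
      "nodes)\n")
  invisible(x)
}

#' Build the (mu_a, mu_s') -> (R1, R2) reflectance database
#'
#' One scatter-only white-Monte-Carlo run per mu_s' node, then analytic
#' Beer-Lambert reweighting over every mu_a node.  Per-node seeds are derived
#' deterministically from `config$seed`, so the build is reproducible.  Nodes
#' whose relative standard error exceeds 10% are counted in the provenance.
#'
#' @param grid a [grid_spec()].
#' @param probe a [probe_geometry()].
#' @param config an [mc_config()]; `n_photons` is the budget per mu_s' node.
#' @param g anisotropy factor used for every node.
#' @return A `reflectance_db`: a data.frame with columns
#'   `mu_a, mu_sp, R1, R2, se1, se2` sorted by (mu_sp, mu_a), carrying a
#'   `provenance` attribute.
#' @export
build_reflectance_database <- function(grid = grid_spec(),
                                       probe = probe_geometry(),
                                       config = mc_config(), g = 0.8) {
  stopifnot(inherits(grid, "grid_spec"))
  nmus <- length(grid$mu_sp)
  rows <- vector("list", nmus)
  n_noisy <- 0L
  for (i in seq_len(nmus)) {
    cfg <- config
    cfg$seed <- config$seed + i - 1
    db <- build_path_database(medium_optics(0, grid$mu_sp[i], g), probe, cfg)
    nd <- length(probe$sds_list)
    B <- .rescale_batch(db$detector_id, db$primary_id, db$path_length,
                        db$weight, db$n_photons, nd, grid$mu_a)
    n_noisy <- n_noisy +
      sum(B$reflectance > 0 & B$se / pmax(B$reflectance, 1e-300) > 0.1)
    rows[[i]] <- data.frame(mu_a = grid$mu_a, mu_sp = grid$mu_sp[i],
                            R1 = B$reflectance[, 1], R2 = B$reflectance[, 2],
                            se1 = B$se[, 1], se2 = B$se[, 2])
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$mu_sp, out$mu_a), ]
  rownames(out) <- NULL
  if (n_noisy > 0)
    warning(n_noisy, " grid entries have relative SE > 10%; ",
            "consider a larger photon budget")
  attr(out, "provenance") <- list(
    geometry_hash = geometry_hash(probe), g = g,
    n_photons_per_node = config$n_photons, seed = config$seed,
    mu_a_nodes = grid$mu_a, mu_sp_nodes = grid$mu_sp, n_noisy = n_noisy)
  class(out) <- c("reflectance_db", "data.frame")
  out
}

#' Bilinear forward interpolation on the reflectance database
#'
#' Fast forward surrogate: bilinear interpolation of (R1, R2) in
#' (mu_a, mu_s').  Exact at grid nodes; queries outside the grid bounds are
#' an error.
#'
#' @param db a `reflectance_db`.
#' @param mu_a,mu_s_prime query coordinates, mm^-1 (vectors of equal length
#'   or length 1, recycled).
#' @return A matrix with one row per query and one column per detector.
#' @export
forward_interpolate <- function(db, mu_a, mu_s_prime) {
  stopifnot(inherits(db, "reflectance_db"))
  prov <- attr(db, "provenance")
  ax <- prov$mu_a_nodes
  sx <- prov$mu_sp_nodes
  n <- max(length(mu_a), length(mu_s_prime))
  mu_a <- rep_len(mu_a, n); mu_s_prime <- rep_len(mu_s_prime, n)
  eps <- 1e-12
  if (any(mu_a < ax[1] - eps | mu_a > ax[length(ax)] + eps |
            mu_s_prime < sx[1] - eps | mu_s_prime > sx[length(sx)] + eps))
    stop("forward_interpolate: query outside the database grid bounds")
  mu_a <- pmin(pmax(mu_a, ax[1]), ax[length(ax)])
  mu_s_prime <- pmin(pmax(mu_s_prime, sx[1]), sx[length(sx)])
  R1 <- matrix(db$R1, nrow = length(ax), ncol = length(sx))  # sorted mu_sp, mu_a
  R2 <- matrix(db$R2, nrow = length(ax), ncol = length(sx))
  ia <- pmin(pmax(findInterval(mu_a, ax), 1), length(ax) - 1)
  is <- pmin(pmax(findInterval(mu_s_prime, sx), 1), length(sx) - 1)
  ta <- (mu_a - ax[ia]) / (ax[ia + 1] - ax[ia])
  ts <- (mu_s_prime - sx[is]) / (sx[is + 1] - sx[is])
  bil <- function(M) {
    (1 - ta) * (1 - ts) * M[cbind(ia, is)] +
      ta * (1 - ts) * M[cbind(ia + 1, is)] +
      (1 - ta) * ts * M[cbind(ia, is + 1)] +
      ta * ts * M[cbind(ia + 1, is + 1)]
  }
  cbind(R1 = bil(R1), R2 = bil(R2))
}

#' Write / read a reflectance database as delimited text
#'
#' Tab-separated columns `mu_a, mu_sp, R1, R2, se1, se2` with a `#` header
#' carrying the provenance (geometry hash, photon budget, seed).  The reader
#' refuses a file whose geometry hash does not match `expect_probe`.
#'
#' @param db a `reflectance_db`.
#' @param path file path.
#' @export
write_reflectance_database <- function(db, path) {
  stopifnot(inherits(db, "reflectance_db"))
  prov <- attr(db, "provenance")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# skindrs reflectance database v1",
               paste0("# geometry: ", prov$geometry_hash),
               paste0("# g: ", format(prov$g)),
               paste0("# n_photons_per_node: ", prov$n_photons_per_node),
               paste0("# seed: ", format(prov$seed)),
               paste0("# n_noisy: ", prov$n_noisy),
               paste0("# columns: mu_a\tmu_sp\tR1\tR2\tse1\tse2")), con)
  write.table(format(as.data.frame(db), digits = 17, scientific = TRUE,
                     trim = TRUE),
              con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
}

#' @rdname write_reflectance_database
#' @param expect_probe optional [probe_geometry()] whose hash must match.
#' @export
read_reflectance_database <- function(path, expect_probe = NULL) {
  hdr <- readLines(path, n = 20)
  hdr <- hdr[startsWith(hdr, "#")]
  get <- function(key) {
    ln <- grep(paste0("^# ", key, ": "), hdr, value = TRUE)
    if (!length(ln)) return(NA_character_)
    sub(paste0("^# ", key, ": "), "", ln[1])
  }
  gh <- get("geometry")
  if (!is.null(expect_probe) && !identical(gh, geometry_hash(expect_probe)))
    stop("geometry hash mismatch: file has '", gh, "'")
  d <- read.table(path, sep = "\t", comment.char = "#",
                  col.names = c("mu_a", "mu_sp", "R1", "R2", "se1", "se2"))
  d <- d[order(d$mu_sp, d$mu_a), ]
  rownames(d) <- NULL
  attr(d, "provenance") <- list(
    geometry_hash = gh, g = as.numeric(get("g")),
    n_photons_per_node = as.numeric(get("n_photons_per_node")),
    seed = as.numeric(get("seed")), n_noisy = as.numeric(get("n_noisy")),
    mu_a_nodes = sort(unique(d$mu_a)), mu_sp_nodes = sort(unique(d$mu_sp)))
  class(d) <- c("reflectance_db", "data.frame")
  d
}
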