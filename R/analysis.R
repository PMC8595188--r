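# Post-processing: near/far strain partition around TE attachments,
# strain concentration ratio, TE tension statistics, tension vs
# orientation angle, and ensemble pooling.

#' Partition membrane elements by distance to the nearest TE attachment
#'
#' An element is NEAR when the Euclidean distance (periodic in z) from its
#' reference centroid to the nearest TE attachment vertex is at most
#' `radius`; the canalicular analysis uses 10.2 nm, twice the fluid
#' lattice interval.
#'
#' @param mesh membrane mesh
#' @param tethers a `canaflow_tethers` set
#' @param radius vicinity radius (nm)
#' @return list: logical `near` per element, counts, and the radius
#' @export
partition_near_far <- function(mesh, tethers, radius = 10.2) {
  ctr <- mesh_centroids(mesh)
  Lz <- mesh$Lz
  att <- tethers$attachment
  if (length(att) == 0) {
    near <- rep(FALSE, nrow(ctr))
  } else {
    ax <- mesh$Vref[att, 1]
    ay <- mesh$Vref[att, 2]
    az <- mesh$Vref[att, 3]
    d2min <- rep(Inf, nrow(ctr))
    for (i in seq_along(att)) {
      dz <- ctr[, 3] - az[i]
      if (!is.na(Lz)) dz <- (dz + Lz / 2) %% Lz - Lz / 2
      d2 <- (ctr[, 1] - ax[i])^2 + (ctr[, 2] - ay[i])^2 + dz^2
      d2min <- pmin(d2min, d2)
    }
    near <- d2min <= radius^2
  }
  if (all(near))
    stop("no FAR elements: vicinity radius ", radius,
         " nm covers the whole membrane")
  list(near = near, n_near = sum(near), n_far = sum(!near), radius = radius)
}

#' Strain concentration ratio near TE attachments
#'
#' Ratio of the median maximum principal strain over NEAR elements to the
#' median over FAR elements.
#'
#' @param strain per-element strain values
#' @param partition result of [partition_near_far()]
#' @return list: `ratio`, `median_near`, `median_far`
#' @export
strain_concentration_ratio <- function(strain, partition) {
  med_n <- median(strain[partition$near], na.rm = TRUE)
  med_f <- median(strain[!partition$near], na.rm = TRUE)
  ratio <- if (!is.finite(med_f) || med_f == 0) NA_real_ else med_n / med_f
  if (is.na(ratio))
    message("FAR median strain is zero or undefined; ratio undefined")
  list(ratio = ratio, median_near = med_n, median_far = med_f)
}

#' TE tension statistics
#'
#' Median of the nonzero tensions, tensions normalized by that median, the
#' taut fraction, and a histogram of the normalized nonzero tensions
#' (20 uniform bins over [0, max]).
#'
#' @param tension per-TE tensions (pN)
#' @param n_bins histogram bin count
#' @return list: `median_nonzero` (pN), `normalized`, `taut_fraction`,
#'   `breaks`, `counts`
#' @export
tension_statistics <- function(tension, n_bins = 20L) {
  nz <- tension[tension > 0]
  if (length(nz) == 0) {
    message("all TEs slack; tension median undefined")
    return(list(median_nonzero = NA_real_, normalized = rep(NA_real_,
                length(tension)), taut_fraction = 0,
                breaks = numeric(0), counts = integer(0)))
  }
  med <- median(nz)
  norm <- tension / med
  breaks <- seq(0, max(norm[tension > 0]), length.out = n_bins + 1L)
  counts <- as.integer(table(cut(norm[tension > 0], breaks,
                                 include.lowest = TRUE)))
  list(median_nonzero = med, normalized = norm,
       taut_fraction = mean(tension > 0), breaks = breaks, counts = counts)
}

#' Tension against TE orientation angle
#'
#' Pairs the no-flow orientation angle theta of each TE with its tension
#' under one flow direction and reports the Spearman rank correlation over
#' the taut TEs (positive under +z flow, negative under -z flow on
#' irregular geometry).
#'
#' @param theta no-flow orientation angles (radians)
#' @param tension per-TE tensions (pN)
#' @param median_tension optional normalization (defaults to the median of
#'   the nonzero tensions)
#' @return list: data frame `pairs` (theta, tension, normalized) and
#'   `spearman` (NA with fewer than 3 taut TEs)
#' @export
tension_vs_angle <- function(theta, tension, median_tension = NULL) {
  if (is.null(median_tension)) {
    nz <- tension[tension > 0]
    median_tension <- if (length(nz)) median(nz) else NA_real_
  }
  taut <- tension > 0
  sp <- if (sum(taut) >= 3 && stats::sd(tension[taut]) > 0 &&
            stats::sd(theta[taut]) > 0) {
    cor(theta[taut], tension[taut], method = "spearman")
  } else NA_real_
  list(pairs = data.frame(theta = theta, tension = tension,
                          normalized = tension / median_tension),
       spearman = sp, n_taut = sum(taut))
}

# per-bundle summary row used by ensemble_summary
summarize_bundle <- function(bundle, radius = 10.2) {
  part <- partition_near_far(bundle$mesh, bundle$tethers, radius)
  scr <- strain_concentration_ratio(bundle$strain, part)
  ts <- tension_statistics(bundle$tension)
  tva <- tension_vs_angle(bundle$theta, bundle$tension, ts$median_nonzero)
  data.frame(seed = bundle$te_seed, direction = bundle$direction,
             median_near = scr$median_near, median_far = scr$median_far,
             ratio = scr$ratio,
             median_tension = ts$median_nonzero,
             taut_fraction = ts$taut_fraction,
             spearman = tva$spearman,
             n_near = part$n_near, n_far = part$n_far)
}

#' Ensemble summary statistics
#'
#' Per-seed, per-direction medians and ratios plus pooled statistics over
#' all bundles (strain values concatenated across seeds and directions
#' before taking medians; tensions likewise).
#'
#' @param ens a `canaflow_ensemble` (or a plain list of result bundles)
#' @param radius vicinity radius (nm)
#' @return list: `per_run` data frame, `pooled` list (medians, ratio,
#'   median tension, taut fraction, n)
#' @export
ensemble_summary <- function(ens, radius = 10.2) {
  bundles <- if (inherits(ens, "canaflow_ensemble")) {
    unlist(lapply(ens$runs, function(r) list(r$pos, r$neg)), recursive = FALSE)
  } else ens
  if (length(bundles) == 0) stop("no result bundles to summarize")
  cfgs <- lapply(bundles, function(b) b$config)
  if (!all(vapply(cfgs, identical, logical(1), y = cfgs[[1]])))
    stop("mixed configurations: bundles are not comparable")
  per <- do.call(rbind, lapply(bundles, summarize_bundle, radius = radius))
  near_all <- numeric(0); far_all <- numeric(0); tens_all <- numeric(0)
  n_te <- 0L
  for (b in bundles) {
    part <- partition_near_far(b$mesh, b$tethers, radius)
    near_all <- c(near_all, b$strain[part$near])
    far_all <- c(far_all, b$strain[!part$near])
    tens_all <- c(tens_all, b$tension)
    n_te <- n_te + length(b$tension)
  }
  med_n <- median(near_all, na.rm = TRUE)
  med_f <- median(far_all, na.rm = TRUE)
  nz <- tens_all[tens_all > 0]
  list(per_run = per,
       pooled = list(
         median_near = med_n, median_far = med_f,
         ratio = med_n / med_f,
         mean_near = mean(near_all, na.rm = TRUE),
         mean_far = mean(far_all, na.rm = TRUE),
         median_tension = if (length(nz)) median(nz) else NA_real_,
         taut_fraction = if (n_te) mean(tens_all > 0) else NA_real_,
         n_elements = length(near_all) + length(far_all),
         n_te = n_te))
}
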