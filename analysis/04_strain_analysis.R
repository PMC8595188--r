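#!/usr/bin/env Rscript
# Post-processes the ensemble exports of 03_ensemble_fsi.R into the
# figure-analog tables:
#   fig2b_tensions.tsv  per-TE tensions by seed and direction
#   fig3a_strain.tsv    NEAR/FAR strain medians, normalized strain ratio
#   fig3b_hist.tsv      histogram of normalized nonzero tensions
#   fig4_angle.tsv      tension vs no-flow orientation angle
#   summary.tsv         per-run and pooled statistics
# Works entirely from the TSV exports (no simulation state needed).

suppressPackageStartupMessages(library(canaflow))
indir <- "results/ensemble"
outdir <- "results"
if (!dir.exists(indir)) stop("run analysis/03_ensemble_fsi.R first")
Lz <- as.numeric(readLines(file.path(indir, "Lz.txt")))
radius <- 10.2

tags <- sub("^strain_", "", sub("\\.tsv$", "",
            list.files(indir, pattern = "^strain_.*tsv$")))
near_all <- c(); far_all <- c(); tens_all <- c()
per <- list(); pairs <- list(); tenrows <- list()
for (tag in tags) {
  st <- read.table(file.path(indir, paste0("strain_", tag, ".tsv")),
                   header = TRUE, sep = "\t")
  te <- read.table(file.path(indir, paste0("tethers_", tag, ".tsv")),
                   header = TRUE, sep = "\t")
  d2min <- rep(Inf, nrow(st))
  for (a in seq_len(nrow(te))) {
    dz <- (st$cz - te$xm_z[a] + Lz / 2) %% Lz - Lz / 2
    d2 <- (st$cx - te$xm_x[a])^2 + (st$cy - te$xm_y[a])^2 + dz^2
    d2min <- pmin(d2min, d2)
  }
  near <- d2min <= radius^2
  med_n <- median(st$max_principal_strain[near])
  med_f <- median(st$max_principal_strain[!near])
  nz <- te$tension[te$tension > 0]
  sp <- if (length(nz) >= 3)
    cor(te$theta[te$tension > 0], te$tension[te$tension > 0],
        method = "spearman") else NA
  dirn <- if (grepl("posz", tag)) "+z" else "-z"
  seed <- as.integer(sub("seed(\\d+)_.*", "\\1", tag))
  per[[tag]] <- data.frame(seed = seed, direction = dirn,
                           median_near = med_n, median_far = med_f,
                           ratio = med_n / med_f,
                           median_tension = median(nz),
                           taut_fraction = mean(te$tension > 0),
                           spearman = sp)
  pairs[[tag]] <- data.frame(seed = seed, direction = dirn,
                             theta = te$theta, tension = te$tension,
                             normalized = te$tension / median(nz))
  tenrows[[tag]] <- data.frame(seed = seed, direction = dirn,
                               id = te$id, tension = te$tension)
  near_all <- c(near_all, st$max_principal_strain[near])
  far_all <- c(far_all, st$max_principal_strain[!near])
  tens_all <- c(tens_all, te$tension)
}

per <- do.call(rbind, per)
pooled_ratio <- median(near_all) / median(far_all)
nzp <- tens_all[tens_all > 0]
med_t <- median(nzp)

wt <- function(df, f) write.table(format(df, digits = 8),
  file.path(outdir, f), sep = "\t", quote = FALSE, row.names = FALSE)

wt(do.call(rbind, tenrows), "fig2b_tensions.tsv")
wt(data.frame(region = c("near", "far"),
              median_strain = c(median(near_all), median(far_all)),
              normalized = c(pooled_ratio, 1)), "fig3a_strain.tsv")
norm <- nzp / med_t
breaks <- seq(0, max(norm), length.out = 21)
wt(data.frame(bin_lo = head(breaks, -1), bin_hi = breaks[-1],
              count = as.integer(table(cut(norm, breaks,
                                           include.lowest = TRUE)))),
   "fig3b_hist.tsv")
wt(do.call(rbind, pairs), "fig4_angle.tsv")
wt(per, "summary.tsv")

cat("pooled median strain ratio NEAR/FAR:", signif(pooled_ratio, 4), "\n")
cat("pooled median nonzero tension:", signif(med_t, 4), "pN\n")
cat("fraction of taut TEs with normalized tension > 5:",
    signif(mean(norm > 5), 3), "\n")
cat("per-run Spearman (tension vs theta):\n")
print(per[, c("seed", "direction", "spearman", "ratio")], digits = 3)
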