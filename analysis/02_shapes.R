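#!/usr/bin/env Rscript

## Outline processing: normalize each outline, pick the number of
## harmonics covering 99.9% of the harmonic power, run the elliptic
## Fourier transform and the PCA, and write the PC-score trait matrix
## used by the inference.

library(fbdshape)

out <- "results/shapes"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
outlines <- read_outlines_csv("results/synthetic/outlines.csv")
message(sprintf("processing %d outlines", length(outlines)))

norm <- lapply(outlines, normalize_outline)
h <- max(vapply(norm, choose_harmonics, 1L, threshold = 0.999))
message(sprintf("harmonics for 99.9%% power: %d", h))

efas <- lapply(norm, efa_transform, n_harmonics = h)
fit <- fit_pca(efa_table(efas))
write_traits_tsv(fit$traits, file.path(out, "pc_traits.tsv"))
write.csv(data.frame(axis = seq_along(fit$basis$eigenvalues),
                     eigenvalue = fit$basis$eigenvalues,
                     cumulative_explained = fit$traits$explained),
          file.path(out, "explained_variance.csv"), row.names = FALSE)

n99 <- which(fit$traits$explained >= 0.99)[1]
message(sprintf("%d axes explain 99%% of shape variation (rank %d total)",
                n99, length(fit$basis$eigenvalues)))

## mean shape and +/-2 sd along the first two axes, as coordinates
shapes <- do.call(rbind, lapply(1:2, function(ax)
  do.call(rbind, lapply(c(-2, 0, 2), function(m) {
    o <- shape_along_axis(fit$basis, ax, m, n_points = 120)
    data.frame(axis = ax, multiple = m, point = seq_len(nrow(o$points)),
               x = o$points[, 1], y = o$points[, 2])
  }))))
write.csv(shapes, file.path(out, "shape_along_axes.csv"), row.names = FALSE)
message("wrote ", out)
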