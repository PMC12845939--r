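#' Biometric error-rate evaluation
#'
#' Computes, over a threshold grid, the False Acceptance Rate
#' (`FAR(t)` = fraction of impostor scores at or below `t`), the False
#' Rejection Rate (`FRR(t)` = fraction of genuine scores above `t`), the
#' Genuine Acceptance Rate (`GAR = 1 - FRR`), and the Equal Error Rate (the
#' `FAR = FRR` operating point, linearly interpolated between the adjacent
#' grid points where `FAR - FRR` changes sign).
#'
#' @param genuine,impostor non-empty numeric score (distance) vectors.
#' @param grid threshold grid (increasing).
#' @return object of class `biometric_eval`: data frame `rates`
#'   (`threshold`, `FAR`, `FRR`, `GAR`), plus `eer` and `eer_threshold`.
#' @export
evaluate_biometrics <- function(genuine, impostor,
                                grid = seq(0, 1, by = 0.002)) {
  if (!length(genuine) || !length(impostor))
    stop("both score sets must be non-empty")
  far <- vapply(grid, function(t) mean(impostor <= t), numeric(1))
  frr <- vapply(grid, function(t) mean(genuine > t), numeric(1))
  ee <- eer_from_rates(far, frr, grid)
  structure(list(rates = data.frame(threshold = grid, FAR = far, FRR = frr,
                                    GAR = 1 - frr),
                 eer = ee$eer, eer_threshold = ee$threshold),
            class = "biometric_eval")
}

#' Equal Error Rate from FAR/FRR curves
#'
#' Linear interpolation of the crossing of `FAR(t)` (non-decreasing in `t`)
#' and `FRR(t)` (non-increasing): on the first grid segment where
#' `FAR - FRR` changes sign, the interpolated common value is returned.
#'
#' @param far,frr rate vectors on a common threshold grid.
#' @param grid the threshold grid (optional, for reporting the EER threshold).
#' @return list with `eer` and `threshold`.
#' @export
eer_from_rates <- function(far, frr, grid = seq_along(far)) {
  d <- far - frr
  if (all(d < 0)) return(list(eer = frr[length(frr)], threshold = grid[length(grid)]))
  i <- which(d >= 0)[1]
  if (d[i] == 0 || i == 1L) return(list(eer = far[i], threshold = grid[i]))
  alpha <- -d[i - 1] / (d[i] - d[i - 1])
  list(eer = far[i - 1] + alpha * (far[i] - far[i - 1]),
       threshold = grid[i - 1] + alpha * (grid[i] - grid[i - 1]))
}

#' @export
print.biometric_eval <- function(x, ...) {
  cat(sprintf("biometric_eval: EER = %.4f%% at threshold %.3f (%d grid points)\n",
              100 * x$eer, x$eer_threshold, nrow(x$rates)))
  invisible(x)
}
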