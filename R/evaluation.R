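#' Per-frame prediction error series
#'
#' Signed component errors (predicted minus ground truth) and their 3D
#' Euclidean norm over the evaluation window only (frames with
#' `window[1] < t <= window[2]`; the training endpoint is excluded).
#'
#' @param pred,truth n x 3 matrices (columns LR, AP, SI), mm, on the same
#'   time grid.
#' @param times Frame times, s.
#' @param window Evaluation window, s; default `c(20, 70)`.
#' @return A data frame of class `error_series` with columns `time_s`,
#'   `e_lr`, `e_ap`, `e_si`, `e_3d`.
#' @export
error_series <- function(pred, truth, times, window = c(20, 70)) {
  pred <- as.matrix(pred); truth <- as.matrix(truth)
  if (nrow(pred) != nrow(truth) || nrow(pred) != length(times))
    stop("MisalignedTimes: prediction and truth must share the time grid")
  sel <- which(times > window[1] & times <= window[2])
  d <- pred[sel, , drop = FALSE] - truth[sel, , drop = FALSE]
  out <- data.frame(time_s = times[sel],
                    e_lr = d[, 1], e_ap = d[, 2], e_si = d[, 3],
                    e_3d = sqrt(rowSums(d^2)))
  class(out) <- c("error_series", "data.frame")
  out
}

#' Percentile error (E90/E95)
#'
#' q-th percentile of absolute errors using linear interpolation between
#' closest order statistics (0-based position `(n - 1) q / 100`, i.e. R's
#' type-7 quantile definition).
#'
#' @param abs_errors Nonempty numeric vector of absolute errors.
#' @param q Percentile in `[0, 100]` (90 or 95 for E90/E95).
#' @return The percentile, mm.
#' @export
percentile_error <- function(abs_errors, q) {
  if (length(abs_errors) == 0) stop("Empty: no errors to summarize")
  unname(stats::quantile(abs_errors, q / 100, type = 7, names = FALSE))
}

#' Reduction ratio
#'
#' `R = 1 - E / A`: the fraction of the tumor's SI excursion removed by
#' tracking, where `E` is the session's SI E90 and `A` the session's
#' peak-to-peak SI displacement of the pseudo-tumor.
#'
#' @param E SI E90, mm.
#' @param A SI pseudo-tumor displacement, mm; must be positive.
#' @return The reduction ratio (<= 1).
#' @export
reduction_ratio <- function(E, A) {
  if (A <= 0) stop("NonpositiveAmplitude: A must be positive")
  1 - E / A
}

#' Phase-to-phase asynchrony residual
#'
#' Norm of the tumor displacement between end-inspiration and
#' end-expiration after subtracting the diaphragm-apex displacement between
#' the same phases: the part of tumor motion a rigidly attached surrogate
#' cannot explain.
#'
#' @param apex_ex,apex_in,tumor_ex,tumor_in 3-vectors (mm) at the two
#'   phases.
#' @return Residual displacement, mm.
#' @export
asynchrony_residual <- function(apex_ex, apex_in, tumor_ex, tumor_in) {
  vnorm((as.numeric(tumor_in) - as.numeric(tumor_ex)) -
          (as.numeric(apex_in) - as.numeric(apex_ex)))
}

#' Surrogate-tumor correlation
#'
#' Pearson correlation between the external surrogate and one tumor
#' coordinate component.
#'
#' @param sig_p Surrogate values.
#' @param tumor_component Tumor coordinate values, same length.
#' @return Correlation coefficient.
#' @export
surrogate_correlation <- function(sig_p, tumor_component) {
  if (length(sig_p) != length(tumor_component) || length(sig_p) < 3)
    stop("surrogate_correlation: need equal lengths >= 3")
  if (stats::sd(sig_p) == 0 || stats::sd(tumor_component) == 0)
    stop("ZeroVariance: constant input")
  stats::cor(sig_p, tumor_component)
}

#' Summarize an error series
#'
#' Per direction and for the 3D norm: signed mean and SD (the norm is
#' nonnegative), and E90/E95 of the absolute values. Optionally adds the
#' session-level SI amplitude `A` and reduction ratio `R`.
#'
#' @param series An [error_series()].
#' @param pseudo_si Optional SI trajectory of the pseudo-tumor over the
#'   session, mm, used for `A` (peak-to-peak) and `R = 1 - E90_SI / A`.
#' @return A list of class `error_summary` with a data frame `by_direction`
#'   (rows LR, AP, SI, 3D) and scalars `A_mm`, `R` (NA when `pseudo_si` is
#'   missing).
#' @export
error_summary <- function(series, pseudo_si = NULL) {
  comp <- list(LR = series$e_lr, AP = series$e_ap, SI = series$e_si,
               `3D` = series$e_3d)
  tab <- do.call(rbind, lapply(names(comp), function(nm) {
    e <- comp[[nm]]
    data.frame(direction = nm, mean_mm = mean(e), sd_mm = stats::sd(e),
               e90_mm = percentile_error(abs(e), 90),
               e95_mm = percentile_error(abs(e), 95))
  }))
  A <- R <- NA_real_
  if (!is.null(pseudo_si)) {
    A <- diff(range(pseudo_si))
    R <- reduction_ratio(tab$e90_mm[tab$direction == "SI"], A)
  }
  structure(list(by_direction = tab, A_mm = A, R = R),
            class = "error_summary")
}

#' @export
print.error_summary <- function(x, ...) {
  cat("Tumor position prediction errors (evaluation window)\n")
  print(x$by_direction, row.names = FALSE, digits = 4)
  if (!is.na(x$A_mm))
    cat(sprintf("SI amplitude A = %.2f mm, reduction ratio R = %.3f\n",
                x$A_mm, x$R))
  invisible(x)
}
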