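#' Half-map cross-validation of overfitting
#'
#' Shakes the model to remove memory of its previous refinement, refines it
#' against half map 1 only, then compares the model-map FSC against the map
#' it was refined against (`FSC_work`) with the FSC against the independent
#' half map (`FSC_test`).  Large per-shell gaps between the two curves, or
#' a sharp drop of `FSC_work` at the refinement resolution cutoff, indicate
#' overfitting: the model has absorbed noise specific to half map 1 and
#' lost predictive power for the data it never saw.  The half maps are
#' first placed on a common amplitude scale ([scale_to_reference()]) so
#' post-processing differences do not masquerade as overfitting.
#'
#' @param model starting [atomic_model()]
#' @param half1,half2 independent half maps on one grid
#' @param restraints a [restraint_set()] or `NULL`
#' @param shake_rms initial random displacement RMSD, Angstrom (default 0.5)
#' @param seed RNG seed for the shake
#' @param n_shells FSC shells
#' @param d_cut refinement resolution cutoff, Angstrom
#' @param weight,n_cycles,mode,gm_scale forwarded to [refine_coords()]
#' @param ... further refinement parameters for [refine_coords()]
#' @return object of class `validation_report`: `fsc_work`, `fsc_test`,
#'   `max_gap`, `mean_gap`, `d_cut`, `model`, `trajectory`
#' @export
cross_validate <- function(model, half1, half2, restraints = NULL,
                           shake_rms = 0.5, seed = 1, n_shells = NULL,
                           d_cut = NULL, weight = 1, n_cycles = 20,
                           mode = c("reciprocal", "real"), gm_scale = 5,
                           ...) {
  mode <- match.arg(mode)
  if (!same_grid(half1, half2)) stop("half maps must share grid geometry")
  half2s <- scale_to_reference(half2, half1, n_shells = n_shells)
  shaken <- shake_model(model, shake_rms, seed)
  run <- refine_coords(shaken, half1, restraints = restraints, d_cut = d_cut,
                       weight = weight, n_cycles = n_cycles, mode = mode,
                       gm_scale = gm_scale, ...)
  if (is.null(d_cut)) d_cut <- 2 * max(half1$voxel)
  fsc_work <- fsc_model_map(run$model, half1, n_shells = n_shells)
  fsc_test <- fsc_model_map(run$model, half2s, n_shells = n_shells)
  stopifnot(all(fsc_work$shell == fsc_test$shell))
  use <- fsc_work$s_min <= 1 / d_cut + 1e-12
  gap <- fsc_work$fsc[use] - fsc_test$fsc[use]
  structure(list(fsc_work = fsc_work, fsc_test = fsc_test,
                 max_gap = max(gap), mean_gap = mean(gap), d_cut = d_cut,
                 model = run$model, trajectory = run$trajectory),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf(paste0("<validation_report> d_cut %.2f A, max gap %.4f, ",
                     "mean gap %.4f\n  FSC_average work %.4f / test %.4f\n"),
              x$d_cut, x$max_gap, x$mean_gap,
              fsc_average(x$fsc_work), fsc_average(x$fsc_test)))
  invisible(x)
}

#' Plot work/test FSC curves of a validation report
#' @param report a `validation_report`
#' @param path optional PNG path; when `NULL`, plots to the active device
#' @export
plot_validation <- function(report, path = NULL) {
  if (!is.null(path)) {
    grDevices::png(path, width = 720, height = 540)
    on.exit(grDevices::dev.off())
  }
  w <- report$fsc_work; t <- report$fsc_test
  graphics::plot(w$s_mid, w$fsc, type = "l", col = "blue", lwd = 2,
                 xlab = "spatial frequency s = 1/d (1/A)", ylab = "FSC",
                 ylim = c(min(0, min(w$fsc), min(t$fsc)), 1))
  graphics::lines(t$s_mid, t$fsc, col = "red", lty = 2, lwd = 2)
  graphics::abline(v = 1 / report$d_cut, lty = 3)
  graphics::abline(h = 0, col = "grey")
  graphics::legend("topright", c("FSC_work", "FSC_test", "refinement cutoff"),
                   col = c("blue", "red", "black"), lty = c(1, 2, 3), lwd = 2)
  invisible(NULL)
}

#' Serialize a validation report to JSON
#' @param report a `validation_report`
#' @param path output path (`NULL` returns the JSON string)
#' @export
validation_to_json <- function(report, path = NULL) {
  obj <- list(d_cut = report$d_cut, max_gap = report$max_gap,
              mean_gap = report$mean_gap,
              fsc_average_work = fsc_average(report$fsc_work),
              fsc_average_test = fsc_average(report$fsc_test),
              shells = data.frame(s_mid = report$fsc_work$s_mid,
                                  fsc_work = report$fsc_work$fsc,
                                  fsc_test = report$fsc_test$fsc,
                                  n_coeffs = report$fsc_work$n_coeffs))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(NULL)
}
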