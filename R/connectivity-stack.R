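# Assembly of the full 13-measure directed connectivity stack for one epoch.

#' Compute all 13 directed connectivity measures on one epoch
#'
#' Runs the complete measure set on a channels x samples epoch and returns one
#' non-negative, zero-diagonal N x N matrix per measure (rows = destination,
#' columns = source). Measures fall into three families:
#' information-theoretic (ANM, IGCI, CDS, RECI, CCE, DI), frequency-domain
#' (GD, PSI, DTF, DCOH, PDC, SGC) and time-domain (LMFIT).
#'
#' @param epoch channels x samples numeric matrix (512 samples at 256 Hz for
#'   the standard pipeline).
#' @param fs sampling rate in Hz.
#' @param order VAR order policy for the MVAR measures ([fit_mvar()]).
#' @param history lag count for DI/CCE.
#' @param measures character subset of measures to compute (default all 13).
#' @return object of class `conn_stack`: named list of matrices, with a
#'   `categories` attribute mapping each measure to its family.
#' @export
compute_stack <- function(epoch, fs = 256, order = "aic", history = 5L,
                          measures = MEASURES) {
  measures <- match.arg(measures, MEASURES, several.ok = TRUE)
  sds <- apply(epoch, 1, stats::sd)
  if (any(sds == 0)) stop("degenerate-signal: constant channel in epoch")
  x <- (epoch - rowMeans(epoch)) / sds

  sp <- NULL
  if (any(c("DTF", "DCOH", "PDC") %in% measures))
    sp <- spectral_transfer(fit_mvar(x, order = order, fs = fs))

  out <- lapply(measures, function(m) {
    res <- tryCatch(switch(m,
      DTF = , DCOH = , PDC = mvar_measure(sp, m),
      SGC = mvar_measure(NULL, "SGC", epoch = x, order = order),
      PSI = , GD = phase_measure(x, m, fs = fs),
      DI = , CCE = info_measure(x, m, history = history),
      ANM = , IGCI = , CDS = , RECI = , LMFIT = pairwise_measure(x, m)),
      error = function(e) stop(m, ": ", conditionMessage(e), call. = FALSE))
    res
  })
  names(out) <- measures
  structure(out, class = "conn_stack",
            categories = MEASURE_CATEGORIES[measures])
}

#' @export
print.conn_stack <- function(x, ...) {
  cats <- attr(x, "categories")
  cat(sprintf("Connectivity stack: %d measures on %d channels\n",
              length(x), nrow(x[[1]])))
  for (fam in unique(cats))
    cat(sprintf("  %s: %s\n", fam, paste(names(x)[cats == fam], collapse = ", ")))
  invisible(x)
}
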