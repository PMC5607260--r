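#' Construct an observation map
#'
#' Links model observables to measured concentrations via per-observable
#' scale and offset parameters, a noise level sigma, and a log-transform
#' flag.  With the log flag on, residuals are formed on the log scale
#' (Gaussian errors after log transformation); sigma is then the standard
#' deviation of the log-scale error.
#'
#' @param observables character vector of observable names.
#' @param scale,offset,sigma numeric, recycled per observable.
#' @param log logical, recycled per observable.
#' @return an [ObservationMap-class].
#' @export
observationMap <- function(observables, scale = 1, offset = 0,
                           sigma = 0.15, log = TRUE) {
  df <- data.frame(observable = observables,
                   scale = rep_len(scale, length(observables)),
                   offset = rep_len(offset, length(observables)),
                   sigma = rep_len(sigma, length(observables)),
                   log = rep_len(log, length(observables)),
                   stringsAsFactors = FALSE)
  obj <- new("ObservationMap", map = df)
  validObject(obj)
  obj
}

#' Default observation map of a model
#'
#' Receptor-level and downstream phospho-observables, unit scale, zero
#' offset, log-normal noise.
#'
#' @param model an [RTKModel-class].
#' @param observables subset of [observableNames()]; defaults to the
#'   receptor phospho-levels and downstream kinases.
#' @param sigma log-scale noise standard deviation.
#' @param offset assay background added to every observation (keeps the
#'   log-scale likelihood finite and continuous when a phospho-pool is
#'   exactly zero, as in reduced model variants).
#' @return an [ObservationMap-class].
#' @export
defaultObservationMap <- function(model,
                                  observables = NULL, sigma = 0.15,
                                  offset = 1) {
  st <- model@structure
  observables <- observables %||%
    c(paste0("p", st$receptors), st$downNames)
  bad <- setdiff(observables, observableNames(model))
  if (length(bad))
    ltStop("schema", paste("unknown observable(s):",
                           paste(bad, collapse = ", ")))
  observationMap(observables, offset = offset, sigma = sigma)
}

setMethod("show", "ObservationMap", function(object) {
  m <- object@map
  cat("ObservationMap for", nrow(m), "observables\n")
  cat("  log-transformed:", sum(m$log), "/", nrow(m), "\n")
  cat("  sigma range:", paste(range(m$sigma), collapse = " - "), "\n")
})

# predicted observation g(x) and residuals for one simulated condition
obsPredict <- function(obsMap, observable, x) {
  m <- obsMap@map
  row <- m[m$observable == observable, , drop = FALSE]
  if (nrow(row) != 1L)
    ltStop("schema", paste0("observable '", observable,
                            "' not in observation map"))
  row$scale * x + row$offset
}

obsResiduals <- function(obsMap, observable, y, g, sigma) {
  m <- obsMap@map
  row <- m[m$observable == observable, , drop = FALSE]
  if (nrow(row) != 1L)
    ltStop("schema", paste0("observable '", observable,
                            "' not in observation map"))
  if (row$log) {
    (log(pmax(y, 1e-12)) - log(pmax(g, 1e-12))) / sigma
  } else {
    (y - g) / sigma
  }
}
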