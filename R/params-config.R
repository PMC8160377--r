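## Model parameter configuration: shipped defaults and YAML loading.

#' Default radiobiological parameter bundle
#'
#' The shipped defaults: tumour LQ-Poisson parameters (rho = 2.8e8
#' cells/cm^3, alpha = 0.12050 /Gy, alpha/beta = 1.6 Gy), urethral LKB
#' parameters for stricture (D50 = 116.7 Gy, m = 0.23, n = 0.3,
#' alpha/beta = 5 Gy), and relative-seriality parameters for bladder
#' (D50 = 80 Gy EQD2, gamma = 2.59, s = 1.3) and rectum (D50 = 80 Gy EQD2,
#' gamma = 1.79, s = 0.75), both with alpha/beta = 3 Gy; all organ weights
#' w_j = 1 (equal clinical importance).
#'
#' @param path Optional YAML config keyed by tissue name overriding the
#'   shipped file.
#' @return A [RadiobioParams-class].
#' @export
defaultRadiobioParams <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "radiobio_params.yaml",
                        package = "rtOutcome")
  readRadiobioParams(path)
}

#' Read radiobiological parameters from a YAML config
#'
#' The file is keyed by tissue name (`tumour`, `urethra`, `bladder`,
#' `rectum`) plus a `weights` map; see the shipped
#' `extdata/radiobio_params.yaml` for the schema.
#'
#' @param path YAML file path.
#' @return A [RadiobioParams-class].
#' @export
readRadiobioParams <- function(path) {
  cfg <- yaml::read_yaml(path)
  need <- c("tumour", "urethra", "bladder", "rectum")
  miss <- setdiff(need, names(cfg))
  if (length(miss))
    stop(sprintf("config is missing tissue sections: %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  num <- function(x) as.numeric(x)  # YAML scalars like "2.8e8" parse as text
  w <- vapply(cfg$weights %||% list(urethra = 1, bladder = 1, rectum = 1),
              num, numeric(1))
  new("RadiobioParams",
      tumour = lqParams(rho = num(cfg$tumour$rho_cl),
                        alpha = num(cfg$tumour$alpha),
                        abRatio = num(cfg$tumour$alpha_beta)),
      urethra = lkbParams(d50 = num(cfg$urethra$d50), m = num(cfg$urethra$m),
                          n = num(cfg$urethra$n),
                          abRatio = num(cfg$urethra$alpha_beta)),
      bladder = serialityParams(d50 = num(cfg$bladder$d50),
                                gamma = num(cfg$bladder$gamma),
                                s = num(cfg$bladder$s),
                                abRatio = num(cfg$bladder$alpha_beta)),
      rectum = serialityParams(d50 = num(cfg$rectum$d50),
                               gamma = num(cfg$rectum$gamma),
                               s = num(cfg$rectum$s),
                               abRatio = num(cfg$rectum$alpha_beta)),
      weights = w)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
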