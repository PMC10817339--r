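#' Dual-retrieval model parameters
#'
#' Construct the six latent-process probabilities of the dual-retrieval model
#' of recall: direct access `D` (verbatim retrieval on test 1), forgetting `F`
#' (loss of direct access across each inter-test interval), reconstruction `R`
#' (gist-based reconstruction when direct access fails), and the familiarity
#' judgments `J1`, `J2`, `J3` (probability that a reconstructed item is judged
#' familiar enough to output on tests 1-3).
#'
#' @param direct_access,forgetting,reconstruction Probabilities in \[0, 1\].
#' @param familiarity_t1,familiarity_t2,familiarity_t3 Per-test familiarity
#'   judgment probabilities in \[0, 1\].
#' @return An object of class `drm_params`: a named numeric vector with
#'   elements `D`, `F`, `J1`, `J2`, `J3`, `R` (the canonical reporting order).
#' @examples
#' drm_params(direct_access = 0.4, forgetting = 0.1, reconstruction = 0.5,
#'            familiarity_t1 = 0.5, familiarity_t2 = 0.6, familiarity_t3 = 0.7)
#' @export
drm_params <- function(direct_access, forgetting, reconstruction,
                       familiarity_t1, familiarity_t2, familiarity_t3) {
  x <- c(D = direct_access, F = forgetting,
         J1 = familiarity_t1, J2 = familiarity_t2, J3 = familiarity_t3,
         R = reconstruction)
  validate_drm_params(x)
  structure(x, class = "drm_params")
}

#' @export
print.drm_params <- function(x, digits = 3, ...) {
  cat("<dual-retrieval parameters>\n")
  print(round(unclass(x), digits))
  invisible(x)
}

# Order used everywhere parameters are serialized or tabulated.
drm_param_names <- function() c("D", "F", "J1", "J2", "J3", "R")

validate_drm_params <- function(x) {
  nm <- drm_param_names()
  if (!all(nm %in% names(x))) {
    stop("parameter vector must contain fields ", paste(nm, collapse = ", "),
         call. = FALSE)
  }
  for (f in nm) {
    v <- x[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      stop("parameter `", f, "` must be a probability in [0, 1], got ",
           format(v), call. = FALSE)
    }
  }
  invisible(x)
}

# Coerce a named vector / one-row data frame / drm_params to the canonical
# named vector, validating the probability domain.
as_drm_params <- function(x) {
  if (inherits(x, "drm_params")) return(x)
  if (is.data.frame(x)) {
    stopifnot(nrow(x) == 1L)
    x <- unlist(x[drm_param_names()])
  }
  x <- x[drm_param_names()]
  validate_drm_params(x)
  structure(stats::setNames(as.numeric(x), drm_param_names()),
            class = "drm_params")
}

#' @export
as.data.frame.drm_params <- function(x, ...) {
  as.data.frame(as.list(unclass(x)))
}

#' Read and write parameter records
#'
#' Parameter records are serialized as delimited text with the fixed header
#' `D,F,J1,J2,J3,R`, one row per condition. An optional leading `condition`
#' column carries labels.
#'
#' @param path File path.
#' @return `read_drm_params()` returns a tibble with a `condition` column
#'   (filled with row numbers when absent) and the six parameter columns.
#' @export
read_drm_params <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  nm <- drm_param_names()
  if (!all(nm %in% names(df))) {
    stop("expected columns ", paste(nm, collapse = ","), " in ", path,
         call. = FALSE)
  }
  if (!"condition" %in% names(df)) df$condition <- as.character(seq_len(nrow(df)))
  for (i in seq_len(nrow(df))) validate_drm_params(unlist(df[i, nm]))
  tibble::as_tibble(df[, c("condition", nm)])
}

#' @param params A `drm_params`, or a data frame with columns
#'   `D,F,J1,J2,J3,R` (plus optional `condition`).
#' @rdname read_drm_params
#' @export
write_drm_params <- function(params, path) {
  if (inherits(params, "drm_params")) params <- as.data.frame(params)
  nm <- drm_param_names()
  keep <- intersect(c("condition", nm), names(params))
  utils::write.csv(params[, keep, drop = FALSE], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
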