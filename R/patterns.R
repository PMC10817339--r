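#' The three-test recall pattern space
#'
#' An item's outcomes over three successive recall tests form one of 8
#' patterns of correct (`C`) and error (`E`) responses. The canonical index of
#' a pattern is `4*[t1 = C] + 2*[t2 = C] + [t3 = C]`, so index 0 is `EEE` and
#' index 7 is `CCC`; test 1 is the most significant bit.
#'
#' @return A tibble with columns `index` (0-7), `pattern` (e.g. `"CCE"`), and
#'   the logical outcome columns `c1`, `c2`, `c3`.
#' @examples
#' recall_patterns()
#' @export
recall_patterns <- function() {
  idx <- 0:7
  c1 <- idx %/% 4L == 1L
  c2 <- (idx %/% 2L) %% 2L == 1L
  c3 <- idx %% 2L == 1L
  lab <- function(b) ifelse(b, "C", "E")
  tibble::tibble(index = idx,
                 pattern = paste0(lab(c1), lab(c2), lab(c3)),
                 c1 = c1, c2 = c2, c3 = c3)
}

pattern_levels <- function() recall_patterns()$pattern

#' Pattern index from per-test outcomes
#'
#' @param c1,c2,c3 Logical (or 0/1) recalled-on-test flags.
#' @return Integer canonical pattern indices in 0-7.
#' @export
pattern_index <- function(c1, c2, c3) {
  4L * as.integer(as.logical(c1)) + 2L * as.integer(as.logical(c2)) +
    as.integer(as.logical(c3))
}

# Internal: 8-vector of pattern probabilities, names in canonical order.
#
# Three latent branches:
#   * verbatim: with probability D the item is directly accessible on test 1
#     (recalled with certainty); the state survives each inter-test interval
#     with probability (1 - F) and, once lost, the item is unrecallable on all
#     remaining tests -> patterns CCC, CCE, CEE only;
#   * gist: with probability (1 - D) * R the item is reconstructable and is
#     output on test t independently with probability Jt -> all 8 patterns;
#   * null: with probability (1 - D) * (1 - R) the item is never recalled.
pattern_prob_vector <- function(params) {
  p <- as_drm_params(params)
  out <- model_pieces(as.numeric(p[drm_param_names()]))$pi
  stats::setNames(out, pattern_levels())
}

#' Model-implied probabilities of the 8 recall patterns
#'
#' Maps dual-retrieval parameters to the probability distribution over the 8
#' correct/error patterns across three recall tests. Recall succeeds either by
#' direct access to verbatim traces (probability `D`, lost between tests with
#' probability `F`, after which the item stays unrecallable), or — when direct
#' access fails — by gist reconstruction (probability `R`) followed by a
#' per-test familiarity judgment (`Jt`). Items in neither branch are never
#' recalled.
#'
#' @param params A [drm_params()] object (or named vector with elements
#'   `D, F, J1, J2, J3, R`).
#' @return A tibble with columns `index`, `pattern`, `probability`; the
#'   probabilities are non-negative and sum to 1.
#' @examples
#' p <- drm_params(0.4, 0.1, 0.5, 0.5, 0.5, 0.5)
#' pattern_probabilities(p)
#' @export
pattern_probabilities <- function(params) {
  pr <- pattern_prob_vector(params)
  dplyr::mutate(recall_patterns()[, c("index", "pattern")],
                probability = unname(pr))
}

#' Simulate three-test recall patterns
#'
#' Draws `n_items` independent recall patterns from the model-implied
#' multinomial distribution.
#'
#' @inheritParams pattern_probabilities
#' @param n_items Number of items (multinomial sample size), at least 1.
#' @param seed Integer seed; draws never touch the global RNG state.
#' @return A tibble with columns `index`, `pattern`, `count`; counts sum to
#'   `n_items`.
#' @examples
#' simulate_patterns(drm_params(1, 0, 0, 0.5, 0.5, 0.5), n_items = 10, seed = 1)
#' @export
simulate_patterns <- function(params, n_items, seed) {
  if (!is.numeric(n_items) || length(n_items) != 1L || n_items < 1) {
    stop("`n_items` must be a positive integer", call. = FALSE)
  }
  pr <- pattern_prob_vector(params)
  counts <- withr::with_seed(seed,
    as.integer(stats::rmultinom(1, size = n_items, prob = pr)))
  dplyr::mutate(recall_patterns()[, c("index", "pattern")], count = counts)
}

# Coerce pattern counts given as a tibble (pattern/count or index/count), a
# named vector, or a bare 8-vector in canonical order, to the canonical
# integer 8-vector.
as_pattern_counts <- function(counts) {
  lev <- pattern_levels()
  if (is.data.frame(counts)) {
    if (!"count" %in% names(counts)) {
      stop("pattern-count data frame needs a `count` column", call. = FALSE)
    }
    key <- if ("pattern" %in% names(counts)) {
      match(counts$pattern, lev)
    } else if ("index" %in% names(counts)) {
      counts$index + 1L
    } else {
      stop("pattern-count data frame needs a `pattern` or `index` column",
           call. = FALSE)
    }
    out <- numeric(8)
    out[key] <- out[key] + counts$count
  } else if (!is.null(names(counts)) && all(lev %in% names(counts))) {
    out <- as.numeric(counts[lev])
  } else {
    stopifnot(length(counts) == 8L)
    out <- as.numeric(counts)
  }
  # non-integer values are allowed so that exact expected counts n * pi can
  # be fit directly; ordinary data are integer
  if (any(!is.finite(out)) || any(out < 0)) {
    stop("pattern counts must be non-negative", call. = FALSE)
  }
  stats::setNames(out, lev)
}

#' Read and write pattern-count records
#'
#' Pattern counts are serialized as 8-column delimited records headed
#' `EEE,EEC,ECE,ECC,CEE,CEC,CCE,CCC` (canonical index order), one row per
#' condition, with an optional leading `condition` column.
#'
#' @param path File path.
#' @return A tibble with `condition`, `pattern`, `index`, `count` (long form).
#' @export
read_pattern_counts <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  lev <- pattern_levels()
  if (!all(lev %in% names(df))) {
    stop("expected columns ", paste(lev, collapse = ","), " in ", path,
         call. = FALSE)
  }
  if (!"condition" %in% names(df)) df$condition <- as.character(seq_len(nrow(df)))
  tidyr::pivot_longer(tibble::as_tibble(df[, c("condition", lev)]),
                      cols = -"condition", names_to = "pattern",
                      values_to = "count") |>
    dplyr::mutate(index = match(.data$pattern, lev) - 1L) |>
    dplyr::select("condition", "pattern", "index", "count")
}

#' @param counts A pattern-count tibble (`pattern`, `count`, optional
#'   `condition`) or named 8-vector.
#' @rdname read_pattern_counts
#' @export
write_pattern_counts <- function(counts, path) {
  lev <- pattern_levels()
  if (is.data.frame(counts) && "condition" %in% names(counts)) {
    wide <- tidyr::pivot_wider(counts[, c("condition", "pattern", "count")],
                               names_from = "pattern", values_from = "count")
    wide <- wide[, c("condition", lev)]
  } else {
    v <- as_pattern_counts(counts)
    wide <- as.data.frame(as.list(v), check.names = FALSE)
  }
  utils::write.csv(wide, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
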