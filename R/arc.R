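#' Count adjacent category repetitions in a recall order
#'
#' A category repetition occurs when a recalled exemplar immediately follows
#' another exemplar from the same category.
#'
#' @param categories Ordered vector of category labels, one per recalled item.
#' @return Integer count; 0 for sequences of length 0 or 1.
#' @examples
#' count_repetitions(c("A", "A", "B", "B"))
#' @export
count_repetitions <- function(categories) {
  n <- length(categories)
  if (n <= 1L) return(0L)
  sum(categories[-1] == categories[-n])
}

# n_i, N, k, m for a recall order (or a bare vector of per-category counts)
category_composition <- function(x) {
  counts <- if (is.null(names(x)) && is.numeric(x)) as.numeric(x)
            else as.numeric(table(x))
  counts <- counts[counts > 0]
  list(n_i = counts, N = sum(counts), k = length(counts),
       m = if (length(counts)) max(counts) else 0)
}

#' Expected category repetitions under a random order
#'
#' The chance-level expectation of adjacent same-category repetitions when the
#' recalled items are output in uniformly random order:
#' `E(R) = sum(n_i^2) / N - 1`, where `n_i` is the number recalled from
#' category i and `N` the total recalled.
#'
#' @param counts Per-category recalled counts, or an ordered vector of
#'   category labels (tabulated internally).
#' @return `E(R)`; errors when no items were recalled.
#' @examples
#' expected_repetitions(c(2, 2))  # 1
#' @export
expected_repetitions <- function(counts) {
  comp <- category_composition(counts)
  if (comp$N < 1) stop("undefined: no items recalled", call. = FALSE)
  sum(comp$n_i^2) / comp$N - 1
}

#' Maximum and minimum possible category repetitions
#'
#' `maxR = N - k` (all categories output contiguously); `minR = 0` when
#' `N + 1 >= 2m`, otherwise `2m - N - 1` (the largest category cannot be fully
#' separated).
#'
#' @inheritParams expected_repetitions
#' @return Named list with `max` and `min`.
#' @export
max_min_repetitions <- function(counts) {
  comp <- category_composition(counts)
  if (comp$N < 1) stop("undefined: no items recalled", call. = FALSE)
  list(max = comp$N - comp$k,
       min = if (comp$N + 1 >= 2 * comp$m) 0L else 2L * comp$m - comp$N - 1L)
}

#' Adjusted ratio of clustering (ARC)
#'
#' Chance-adjusted index of category clustering in a recall output order:
#' `(R - E(R)) / (maxR - E(R))` when observed repetitions exceed chance, and
#' `(R - E(R)) / (E(R) - minR)` when below chance, so that 1 indicates perfect
#' clustering, 0 chance clustering, and -1 maximal anti-clustering. `R = E(R)`
#' is scored 0. ARC is undefined — returned as `NA` with `defined = FALSE` —
#' when fewer than two items or only one category was recalled, or when the
#' applicable denominator is zero; undefined values are excluded from
#' condition means downstream.
#'
#' @param categories Ordered category labels of one test's recalled items
#'   (intrusions removed; within-test duplicates already collapsed).
#' @return A one-row tibble: `n_recalled`, `k_categories`, `repetitions`,
#'   `expected`, `max_rep`, `min_rep`, `arc`, `defined`.
#' @examples
#' arc(c("A", "A", "B", "B"))   # perfect clustering, arc = 1
#' arc(c("A", "B", "A", "B"))   # maximal anti-clustering, arc = -1
#' @export
arc <- function(categories) {
  comp <- category_composition(categories)
  R <- count_repetitions(categories)
  if (comp$N <= 1L || comp$k == 1L) {
    return(tibble::tibble(
      n_recalled = comp$N, k_categories = comp$k, repetitions = as.integer(R),
      expected = if (comp$N >= 1) sum(comp$n_i^2) / comp$N - 1 else NA_real_,
      max_rep = if (comp$N >= 1) comp$N - comp$k else NA_integer_,
      min_rep = NA_integer_, arc = NA_real_, defined = FALSE))
  }
  ER <- expected_repetitions(categories)
  mm <- max_min_repetitions(categories)
  val <- if (R > ER) {
    if (mm$max - ER == 0) NA_real_ else (R - ER) / (mm$max - ER)
  } else if (R < ER) {
    if (ER - mm$min == 0) NA_real_ else (R - ER) / (ER - mm$min)
  } else 0
  tibble::tibble(n_recalled = comp$N, k_categories = comp$k,
                 repetitions = as.integer(R), expected = ER,
                 max_rep = as.integer(mm$max), min_rep = as.integer(mm$min),
                 arc = val, defined = !is.na(val))
}

#' Per-participant, per-test ARC from a trial-level table
#'
#' Reconstructs each participant's recall output order on each test from the
#' trial-level table and computes ARC. Rows with a missing output position
#' (items not recalled on that test) are dropped.
#'
#' @param trials Trial-level tibble with columns `participant_id`,
#'   `organization`, `jol_condition`, `category`, and
#'   `output_position_t1..t3` (as produced by [generate_experiment()]).
#' @param tests Which recall tests to score (default all three).
#' @return A tibble with one row per participant x test, carrying the
#'   condition labels and the [arc()] columns.
#' @export
arc_by_participant <- function(trials, tests = 1:3) {
  purrr::list_rbind(purrr::map(tests, function(t) {
    pos_col <- paste0("output_position_t", t)
    stopifnot(pos_col %in% names(trials))
    recalled <- trials[!is.na(trials[[pos_col]]), ]
    dplyr::group_by(recalled, .data$participant_id, .data$organization,
                    .data$jol_condition) |>
      dplyr::group_modify(function(df, key) {
        ord <- order(df[[pos_col]])
        arc(as.character(df$category[ord]))
      }) |>
      dplyr::ungroup() |>
      dplyr::mutate(test = t, .after = "participant_id")
  }))
}
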