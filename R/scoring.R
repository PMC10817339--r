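#' Score one recall transcript against the study list
#'
#' Matches a participant's ordered typed responses for one test to the study
#' words. Responses are normalized (lower-cased, trimmed, internal whitespace
#' collapsed) and matched by exact normalized equality or, failing that, by
#' smallest edit distance within `tolerance` (spelling leniency); ties go to
#' the study word listed first. Each study word can be matched at most once,
#' within-test duplicate responses are collapsed to their first occurrence,
#' and unmatched responses are counted as intrusions.
#'
#' @param responses Character vector of typed responses, in output order.
#' @param study_words Character vector of study-list words (presentation
#'   order).
#' @param tolerance Maximum Levenshtein distance for a non-exact match
#'   (default 1); 0 demands exact normalized equality.
#' @return A tibble with one row per study word: `word`, `recalled`,
#'   `output_position` (`NA` when not recalled). The attribute `"intrusions"`
#'   holds the unmatched normalized responses.
#' @examples
#' score_recall(c("Apple ", "aple", "zebra"), c("apple", "pear"))
#' @export
score_recall <- function(responses, study_words, tolerance = 1) {
  if (length(study_words) == 0) stop("study list is empty", call. = FALSE)
  norm <- function(x) gsub("\\s+", " ", trimws(tolower(x)))
  resp <- norm(as.character(responses))
  resp <- resp[resp != ""]
  resp <- resp[!duplicated(resp)]
  study_norm <- norm(study_words)
  matched <- rep(NA_integer_, length(study_words))  # output position per word
  intrusions <- character()
  pos <- 0L
  for (r in resp) {
    open <- which(is.na(matched))
    if (!length(open)) { intrusions <- c(intrusions, r); next }
    hit <- open[study_norm[open] == r]
    if (!length(hit) && tolerance > 0) {
      d <- utils::adist(r, study_norm[open])[1, ]
      if (min(d) <= tolerance) hit <- open[which(d == min(d))]
    }
    if (length(hit)) {
      pos <- pos + 1L
      matched[hit[1]] <- pos       # ties: first-listed study word wins
    } else {
      intrusions <- c(intrusions, r)
    }
  }
  out <- tibble::tibble(word = study_words,
                        recalled = !is.na(matched),
                        output_position = matched)
  attr(out, "intrusions") <- intrusions
  out
}

#' Score a table of recall transcripts
#'
#' Applies [score_recall()] to every participant x test transcript and joins
#' the result back onto the participants' study lists, yielding the
#' trial-level recalled/output-position columns consumed by
#' [build_patterns()] and [fit_conditions()].
#'
#' @param transcripts Tibble with columns `participant_id`, `test` (1-3),
#'   `response_order`, `response`.
#' @param study_lists Tibble with columns `participant_id`, `word` and any
#'   further per-item columns (e.g. `category`, `serial_position`,
#'   `organization`, `jol_condition`), one row per studied item.
#' @inheritParams score_recall
#' @return `study_lists` augmented with `recalled_t1..t3` and
#'   `output_position_t1..t3`. Missing transcripts score as nothing recalled.
#' @export
score_transcripts <- function(transcripts, study_lists, tolerance = 1) {
  need <- c("participant_id", "test", "response_order", "response")
  if (!all(need %in% names(transcripts))) {
    stop("transcripts need columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  out <- study_lists
  for (t in 1:3) {
    out[[paste0("recalled_t", t)]] <- FALSE
    out[[paste0("output_position_t", t)]] <- NA_integer_
  }
  for (pid in unique(study_lists$participant_id)) {
    rows <- which(out$participant_id == pid)
    words <- out$word[rows]
    for (t in 1:3) {
      tr <- transcripts[transcripts$participant_id == pid &
                          transcripts$test == t, ]
      if (!nrow(tr)) next
      sc <- score_recall(tr$response[order(tr$response_order)], words,
                         tolerance = tolerance)
      out[[paste0("recalled_t", t)]][rows] <- sc$recalled
      out[[paste0("output_position_t", t)]][rows] <- sc$output_position
    }
  }
  out
}

#' Aggregate trial-level flags into pattern counts
#'
#' Converts each item's three recalled flags to its canonical recall pattern
#' and tallies patterns within grouping columns (by default the design cell).
#'
#' @param trials Trial-level tibble with `recalled_t1`, `recalled_t2`,
#'   `recalled_t3`.
#' @param by Character vector of grouping columns present in `trials`;
#'   grouping values are pasted with `"."` into a `condition` label. Use
#'   `by = character()` to pool everything.
#' @return Long tibble `condition`, `pattern`, `index`, `count`; counts in a
#'   condition sum to its number of item rows.
#' @export
build_patterns <- function(trials, by = intersect(c("organization",
                                                    "jol_condition"),
                                                  names(trials))) {
  need <- paste0("recalled_t", 1:3)
  miss <- setdiff(need, names(trials))
  if (length(miss)) {
    stop("missing recall flag columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  lev <- pattern_levels()
  df <- dplyr::mutate(trials,
    condition = if (length(by)) {
      do.call(paste, c(lapply(by, function(v) trials[[v]]), sep = "."))
    } else "all",
    index = pattern_index(.data$recalled_t1, .data$recalled_t2,
                          .data$recalled_t3),
    pattern = factor(lev[.data$index + 1L], levels = lev))
  dplyr::count(df, .data$condition, .data$pattern, .drop = FALSE,
               name = "count") |>
    dplyr::mutate(pattern = as.character(.data$pattern),
                  index = match(.data$pattern, lev) - 1L) |>
    dplyr::select("condition", "pattern", "index", "count")
}

#' Per-participant recall summaries
#'
#' @param trials Trial-level tibble with recall flags and the design columns.
#' @return One row per participant: condition labels, `recall_t1..t3`
#'   (proportion of studied items recalled on each test) and `mean_recall`.
#' @export
participant_summaries <- function(trials) {
  dplyr::group_by(trials, .data$participant_id, .data$organization,
                  .data$jol_condition) |>
    dplyr::summarise(n_items = dplyr::n(),
                     recall_t1 = mean(.data$recalled_t1),
                     recall_t2 = mean(.data$recalled_t2),
                     recall_t3 = mean(.data$recalled_t3),
                     .groups = "drop") |>
    dplyr::mutate(mean_recall = (.data$recall_t1 + .data$recall_t2 +
                                   .data$recall_t3) / 3)
}

#' Screen out unusually high recallers
#'
#' Flags participants whose mean recall lies more than 1.5 interquartile
#' ranges above their cell's median. As printed, the rule is upper-sided and
#' anchored at the median (not Tukey's quartile-anchored fences); quartiles
#' use linear interpolation (`stats::quantile()` type 7). A symmetric variant
#' that also excludes low outliers (below median - 1.5 IQR) is available via
#' `symmetric = TRUE`.
#'
#' @param summaries Output of [participant_summaries()] (or any tibble with
#'   `participant_id`, `organization`, `jol_condition`, `mean_recall`).
#' @param symmetric Also exclude the lower tail.
#' @return `summaries` with an `included` flag; the `"exclusions"` attribute
#'   is a tibble logging every excluded participant with the cell threshold.
#'   Cells with fewer than 4 participants are left unscreened with a warning.
#' @export
outlier_filter <- function(summaries, symmetric = FALSE) {
  out <- dplyr::group_by(summaries, .data$organization, .data$jol_condition) |>
    dplyr::group_modify(function(df, key) {
      if (nrow(df) < 4) {
        warning("cell ", paste(key, collapse = "."), " has fewer than 4 ",
                "participants; outlier screen skipped", call. = FALSE)
        df$included <- TRUE
        df$threshold <- NA_real_
        return(df)
      }
      q <- stats::quantile(df$mean_recall, c(0.25, 0.5, 0.75), type = 7)
      iqr <- q[[3]] - q[[1]]
      hi <- q[[2]] + 1.5 * iqr
      keep <- df$mean_recall <= hi
      if (symmetric) keep <- keep & df$mean_recall >= q[[2]] - 1.5 * iqr
      df$included <- keep
      df$threshold <- hi
      df
    }) |>
    dplyr::ungroup()
  excl <- dplyr::filter(out, !.data$included)[,
    c("participant_id", "organization", "jol_condition", "mean_recall",
      "threshold")]
  out <- dplyr::select(out, -"threshold")
  attr(out, "exclusions") <- excl
  out
}
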