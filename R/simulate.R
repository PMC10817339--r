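#' Configuration for a synthetic recall experiment
#'
#' Describes a 2 (list organization: blocked, randomized) x 3 (JOL condition:
#' item, list, none) between-participants categorized-list experiment with
#' three successive free-recall tests, from which [generate_experiment()]
#' simulates complete trial-level data. Defaults emulate a 240-participant
#' design with 40 study words (8 exemplars from each of 5 taxonomic
#' categories), item-level judgments of learning on a 0-100 scale, list-level
#' judgments on a 0-8 scale, and randomized orders whose same-category runs
#' never exceed 3.
#'
#' @param n_participants Total participants, allocated to the 6 cells
#'   balanced within one.
#' @param n_categories,exemplars_per_category List composition; the study
#'   list has `n_categories * exemplars_per_category` words.
#' @param max_run_length Longest same-category run permitted in randomized
#'   presentation orders.
#' @param true_params Named list mapping each cell `"<organization>.<jol>"`
#'   to its generating [drm_params()]. The defaults are per-cell estimates
#'   typical of this design, so the six cells differ (e.g. the randomized
#'   item-JOL cell has a higher test-1 familiarity judgment than the
#'   randomized no-JOL cell).
#' @param item_jol_mean,item_jol_sd Normal location/spread for item JOLs
#'   before rounding and clipping to 0-100.
#' @param list_jol_means,list_jol_sds Per-organization location/spread for
#'   list JOLs before rounding and clipping to 0-8.
#' @param clustering_weight In \[0, 1\]: probability that the simulated
#'   recall output stays within the current category when possible (0 =
#'   uniform output order, 1 = perfectly clustered output).
#' @param seed Integer master seed; the whole experiment is a deterministic
#'   function of the configuration.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(n_participants = 240,
                              n_categories = 5,
                              exemplars_per_category = 8,
                              max_run_length = 3,
                              true_params = default_true_params(),
                              item_jol_mean = 50, item_jol_sd = 25,
                              list_jol_means = c(blocked = 4.89,
                                                 randomized = 3.73),
                              list_jol_sds = c(blocked = 1.19,
                                               randomized = 1.06),
                              clustering_weight = 0.5,
                              seed = 1) {
  cfg <- list(n_participants = as.integer(n_participants),
              n_categories = as.integer(n_categories),
              exemplars_per_category = as.integer(exemplars_per_category),
              organizations = c("blocked", "randomized"),
              jol_conditions = c("item", "list", "none"),
              max_run_length = as.integer(max_run_length),
              true_params = lapply(true_params, as_drm_params),
              item_jol_mean = item_jol_mean, item_jol_sd = item_jol_sd,
              list_jol_means = list_jol_means, list_jol_sds = list_jol_sds,
              clustering_weight = clustering_weight,
              seed = as.integer(seed))
  if (cfg$n_participants < 1) stop("need at least one participant", call. = FALSE)
  if (cfg$item_jol_mean < 0 || cfg$item_jol_mean > 100) {
    stop("item JOL mean must lie on the 0-100 scale", call. = FALSE)
  }
  if (any(cfg$list_jol_means < 0 | cfg$list_jol_means > 8)) {
    stop("list JOL means must lie on the 0-8 scale", call. = FALSE)
  }
  if (clustering_weight < 0 || clustering_weight > 1) {
    stop("`clustering_weight` must be in [0, 1]", call. = FALSE)
  }
  cells <- as.vector(outer(cfg$organizations, cfg$jol_conditions, paste,
                           sep = "."))
  missing <- setdiff(cells, names(cfg$true_params))
  if (length(missing)) {
    stop("`true_params` missing cells: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  structure(cfg, class = "experiment_config")
}

#' Default generating parameters for the six design cells
#'
#' One [drm_params()] per `"<organization>.<jol>"` cell. Values are typical
#' per-cell estimates for this design: direct access around 0.25-0.42,
#' forgetting 0.05-0.10, reconstruction 0.10-0.20, and familiarity judgments
#' rising across tests, with the randomized item-JOL cell's `J1` elevated
#' relative to its no-JOL counterpart (the JOL-reactivity signature the
#' pipeline is built to detect).
#'
#' @export
default_true_params <- function() {
  mk <- function(D, F, J1, J2, J3, R) drm_params(D, F, R, J1, J2, J3)
  list(
    blocked.item    = mk(0.42, 0.05, 0.40, 0.52, 0.79, 0.19),
    blocked.list    = mk(0.42, 0.10, 0.50, 0.69, 0.78, 0.20),
    blocked.none    = mk(0.40, 0.05, 0.42, 0.62, 0.84, 0.20),
    randomized.item = mk(0.37, 0.06, 0.54, 0.64, 0.84, 0.20),
    randomized.list = mk(0.25, 0.09, 0.71, 0.74, 0.91, 0.10),
    randomized.none = mk(0.33, 0.06, 0.34, 0.58, 0.84, 0.15)
  )
}

#' Build one participant's study lists
#'
#' Blocked organization presents each category's exemplars consecutively
#' (category order and within-category order random); randomized organization
#' rejection-samples a global order in which no more than `max_run_length`
#' consecutive words share a category, then cuts it into lists of
#' `exemplars_per_category` words.
#'
#' @param config An [experiment_config()].
#' @param organization `"blocked"` or `"randomized"`.
#' @param seed Integer seed for this participant's orders.
#' @return A tibble with `list_index`, `serial_position`, `word`, `category`.
#' @export
build_lists <- function(config, organization = c("blocked", "randomized"),
                        seed = config$seed) {
  organization <- match.arg(organization)
  ncat <- config$n_categories
  nex <- config$exemplars_per_category
  if (organization == "randomized" && ncat == 1L && nex > config$max_run_length) {
    stop("run-length constraint unsatisfiable: a single category cannot be ",
         "interleaved", call. = FALSE)
  }
  cats <- sprintf("cat%02d", seq_len(ncat))
  items <- tidyr::expand_grid(category = cats, exemplar = seq_len(nex)) |>
    dplyr::mutate(word = paste0(.data$category, "_", .data$exemplar))
  n_items <- nrow(items)
  ord <- withr::with_seed(seed, {
    if (organization == "blocked") {
      cat_order <- sample(cats)
      unlist(lapply(cat_order, function(ct) sample(which(items$category == ct))))
    } else {
      ok <- FALSE
      for (try in seq_len(10000L)) {
        o <- sample.int(n_items)
        if (max(rle(items$category[o])$lengths) <= config$max_run_length) {
          ok <- TRUE
          break
        }
      }
      if (!ok) stop("run-length constraint unsatisfiable for this ",
                    "configuration", call. = FALSE)
      o
    }
  })
  tibble::tibble(
    list_index = rep(seq_len(n_items %/% nex + (n_items %% nex > 0)),
                     each = nex, length.out = n_items),
    serial_position = seq_len(n_items),
    word = items$word[ord],
    category = items$category[ord])
}

#' Simulate three-test recall outcomes and output orders
#'
#' Each item's correct/error pattern over the three tests is drawn from the
#' dual-retrieval model ([pattern_probabilities()]); within each test the
#' output order of the recalled items follows a category-biased sequential
#' draw: with probability `clustering_weight` the next output stays in the
#' just-output category when any of its recalled items remain, otherwise it is
#' uniform over all remaining recalled items.
#'
#' @param study_list Tibble from [build_lists()].
#' @param params Generating [drm_params()].
#' @param clustering_weight Category-contiguity bias in \[0, 1\].
#' @param seed Integer seed.
#' @return `study_list` augmented with `recalled_t1..t3` (logical) and
#'   `output_position_t1..t3` (integer, `NA` when not recalled).
#' @export
simulate_recall <- function(study_list, params, clustering_weight = 0.5,
                            seed = 1) {
  pr <- pattern_prob_vector(params)
  n <- nrow(study_list)
  out <- study_list
  withr::with_seed(seed, {
    idx <- sample(0:7, n, replace = TRUE, prob = pr)
    for (t in 1:3) {
      bit <- c(4L, 2L, 1L)[t]
      rec <- (idx %/% bit) %% 2L == 1L
      out[[paste0("recalled_t", t)]] <- rec
      pos <- rep(NA_integer_, n)
      remaining <- which(rec)
      cur_cat <- NA_character_
      p <- 0L
      while (length(remaining)) {
        p <- p + 1L
        same <- if (is.na(cur_cat)) integer(0) else
          remaining[study_list$category[remaining] == cur_cat]
        pick <- if (length(same) && stats::runif(1) < clustering_weight) {
          same[sample.int(length(same), 1)]
        } else {
          remaining[sample.int(length(remaining), 1)]
        }
        pos[pick] <- p
        cur_cat <- study_list$category[pick]
        remaining <- setdiff(remaining, pick)
      }
      out[[paste0("output_position_t", t)]] <- pos
    }
  })
  out
}

#' Simulate judgment-of-learning ratings
#'
#' Item-level JOLs are integer-rounded normal draws clipped to the 0-100
#' scale; list-level JOLs are integer-rounded normal draws clipped to the 0-8
#' scale, with organization-specific means.
#'
#' @param config An [experiment_config()].
#' @param condition `"item"` or `"list"`.
#' @param organization `"blocked"` or `"randomized"` (sets the list-JOL mean).
#' @param n Number of ratings to draw.
#' @param seed Integer seed.
#' @return Integer vector of length `n` on the condition's scale.
#' @export
simulate_jols <- function(config, condition = c("item", "list"),
                          organization = c("blocked", "randomized"),
                          n, seed = config$seed) {
  condition <- match.arg(condition)
  organization <- match.arg(organization)
  withr::with_seed(seed, {
    if (condition == "item") {
      raw <- stats::rnorm(n, config$item_jol_mean, config$item_jol_sd)
      as.integer(pmin(pmax(round(raw), 0), 100))
    } else {
      raw <- stats::rnorm(n, config$list_jol_means[[organization]],
                          config$list_jol_sds[[organization]])
      as.integer(pmin(pmax(round(raw), 0), 8))
    }
  })
}

#' Generate a complete synthetic experiment
#'
#' Allocates participants to the six design cells (balanced within one),
#' builds each participant's study lists, draws JOLs appropriate to the cell,
#' and simulates three-test recall outcomes and output orders from the cell's
#' generating parameters. The result is a tidy trial-level table, one row per
#' participant x study item, fully reproducible from `config$seed`.
#'
#' @param config An [experiment_config()].
#' @return A tibble with columns `participant_id`, `organization`,
#'   `jol_condition`, `list_index`, `serial_position`, `word`, `category`,
#'   `item_jol` (present iff the item-JOL cell), `list_jol` (attached to each
#'   list's final row, present iff the list-JOL cell), `recalled_t1..t3`,
#'   `output_position_t1..t3`.
#' @examples
#' cfg <- experiment_config(n_participants = 12, seed = 42)
#' trials <- generate_experiment(cfg)
#' dplyr::count(trials, organization, jol_condition) # 40 rows per participant
#' @export
generate_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  cells <- as.vector(outer(config$organizations, config$jol_conditions,
                           paste, sep = "."))
  cell_of <- rep(cells, length.out = config$n_participants)
  seeds <- withr::with_seed(config$seed,
    matrix(sample.int(.Machine$integer.max - 1L,
                      config$n_participants * 3L),
           ncol = 3L))
  nex <- config$exemplars_per_category
  n_items <- config$n_categories * nex
  purrr::list_rbind(purrr::map(seq_len(config$n_participants), function(i) {
    cell <- cell_of[i]
    org <- strsplit(cell, ".", fixed = TRUE)[[1]][1]
    jol <- strsplit(cell, ".", fixed = TRUE)[[1]][2]
    lists <- build_lists(config, org, seed = seeds[i, 1])
    trial <- simulate_recall(lists, config$true_params[[cell]],
                             config$clustering_weight, seed = seeds[i, 2])
    trial$item_jol <- NA_integer_
    trial$list_jol <- NA_integer_
    if (jol == "item") {
      trial$item_jol <- simulate_jols(config, "item", org, n = n_items,
                                      seed = seeds[i, 3])
    } else if (jol == "list") {
      n_lists <- max(trial$list_index)
      lj <- simulate_jols(config, "list", org, n = n_lists,
                          seed = seeds[i, 3])
      at_end <- trial$serial_position %% nex == 0
      trial$list_jol[at_end] <- lj[trial$list_index[at_end]]
    }
    dplyr::bind_cols(
      tibble::tibble(participant_id = i, organization = org,
                     jol_condition = jol),
      trial)
  }))
}
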