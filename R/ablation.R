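#' Ablation and structural grids
#'
#' Builds the named configuration grids used to probe the architecture:
#'
#' * `"directions"` (3 rows): strip convolutions restricted to 1 x K only,
#'   K x 1 only, or both directions.
#' * `"branches"` (7 rows): every non-empty subset of the three kernel
#'   branches.
#' * `"components"` (6 rows): subsets of \{convolution, self-attention,
#'   residual\}; a residual connection always has a partner component, so
#'   the residual-only and residual+nothing rows are excluded.
#' * `"channels"` (8 rows): 10, 20, ..., 80 expansion channels with one
#'   block.
#' * `"efcm_units"` (5 rows): 1 to 5 blocks.
#'
#' @param name Grid name.
#' @param base A [model_config()] providing all non-varied fields.
#' @return A tibble with `config_id` and a `config` list-column of
#'   [model_config()] objects.
#' @export
ablation_grid <- function(name = c("directions", "branches", "components",
                                   "channels", "efcm_units"),
                          base = model_config()) {
  name <- match.arg(name)
  kern <- vapply(base$branches, function(b) b$kernel, integer(1))
  rebranch <- function(...) {
    lapply(seq_along(kern), function(i) branch_spec(index = i, kernel = kern[i], ...))
  }
  reconfig <- function(branches = NULL, ...) {
    cfg <- base
    dots <- list(...)
    for (nm in names(dots)) cfg[[nm]] <- dots[[nm]]
    if (!is.null(branches)) cfg$branches <- branches
    cfg
  }
  rows <- switch(
    name,
    directions = tibble::tibble(
      config_id = c("conv_1xK_only", "conv_Kx1_only", "conv_both"),
      config = list(reconfig(rebranch(directions = "time_only")),
                    reconfig(rebranch(directions = "space_only")),
                    reconfig(rebranch(directions = "both")))),
    branches = {
      subsets <- list(1L, 2L, 3L, c(1L, 2L), c(1L, 3L), c(2L, 3L), 1:3)
      tibble::tibble(
        config_id = vapply(subsets, function(s) {
          paste0("branch_", paste(s, collapse = ""))
        }, character(1)),
        config = lapply(subsets, function(s) {
          reconfig(lapply(s, function(i) branch_spec(index = i, kernel = kern[i])))
        }))
    },
    components = {
      cases <- list(conv            = c(TRUE,  FALSE, FALSE),
                    attn            = c(FALSE, TRUE,  FALSE),
                    conv_resid      = c(TRUE,  FALSE, TRUE),
                    attn_resid      = c(FALSE, TRUE,  TRUE),
                    conv_attn       = c(TRUE,  TRUE,  FALSE),
                    conv_attn_resid = c(TRUE,  TRUE,  TRUE))
      tibble::tibble(
        config_id = names(cases),
        config = lapply(cases, function(cs) {
          reconfig(rebranch(use_conv = cs[1], use_attention = cs[2],
                            use_residual = cs[3]))
        }))
    },
    channels = {
      ch <- seq(10L, 80L, by = 10L)
      tibble::tibble(config_id = paste0("channels_", ch),
                     config = lapply(ch, function(C) {
                       reconfig(expansion_channels = C, n_efcm = 1L)
                     }))
    },
    efcm_units = {
      u <- 1:5
      tibble::tibble(config_id = paste0("units_", u),
                     config = lapply(u, function(n) reconfig(n_efcm = n)))
    })
  rows
}

#' Run an ablation grid under cross-validation
#'
#' For each configuration in the grid: a full [kfold_cv()] on the supplied
#' training data, reported as mean +/- sd of accuracy and macro
#' precision/recall across folds.
#'
#' @param grid Output of [ablation_grid()], or a named list of
#'   [model_config()]s.
#' @param ds Training `taste_dataset`.
#' @param tconfig A [train_config()].
#' @param verbose Print per-configuration progress.
#' @return A `taste_ablation` tibble: one row per configuration with
#'   mean/sd columns; the per-fold table is kept in attribute `"folds"`.
#' @export
run_ablation <- function(grid, ds, tconfig, verbose = FALSE) {
  if (!tibble::is_tibble(grid)) {
    assert_that(is.list(grid) && !is.null(names(grid)),
                "grid must be an ablation_grid() tibble or a named list of configs")
    grid <- tibble::tibble(config_id = names(grid), config = unname(grid))
  }
  assert_that(all(c("config_id", "config") %in% names(grid)),
              "grid needs config_id and config columns")
  rows <- vector("list", nrow(grid))
  fold_rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cfg <- grid$config[[i]]
    assert_that(inherits(cfg, "model_config"), "grid entries must be model_configs")
    if (verbose) message(sprintf("[%d/%d] %s", i, nrow(grid), grid$config_id[i]))
    cv <- kfold_cv(ds, cfg, tconfig, keep_models = FALSE, verbose = FALSE)
    f <- cv$folds
    rows[[i]] <- tibble::tibble(
      config_id = grid$config_id[i],
      accuracy_mean = mean(f$accuracy), accuracy_sd = stats::sd(f$accuracy),
      precision_mean = mean(f$precision_macro),
      precision_sd = stats::sd(f$precision_macro),
      recall_mean = mean(f$recall_macro), recall_sd = stats::sd(f$recall_macro))
    fold_rows[[i]] <- dplyr::mutate(f, config_id = grid$config_id[i],
                                    .before = 1)
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "folds") <- dplyr::bind_rows(fold_rows)
  class(out) <- c("taste_ablation", class(out))
  out
}
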