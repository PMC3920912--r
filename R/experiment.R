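#' Experiment configuration
#'
#' Describes one end-to-end run of the incomplete-label protocol:
#' corrupt the training labels at each deletion fraction `p`, restore
#' missing labels, modify the training set, train a Binary-Relevance
#' classifier, and evaluate on a clean held-out test set. A development
#' split (20% of the training documents by default) carved from the
#' *corrupted* training set drives the grid search over `(k, T)` — no
#' oracle labels leak into model selection.
#'
#' @param dataset a complete-labeled [multilabel_dataset] or a
#'   [synthetic_spec()] to generate one.
#' @param p_grid deletion fractions to sweep (0 is always added as the
#'   uncorrupted reference row).
#' @param restorer `"wknn"`, `"softsl"` or `"none"`.
#' @param mode `"add"`, `"del"` or `"none"`.
#' @param k_grid neighbour counts searched.
#' @param T_grid acceptance thresholds searched (WkNN; SoftSL uses its
#'   fixed `T`).
#' @param mu SoftSL graph-term weight.
#' @param softsl_T fixed SoftSL acceptance threshold.
#' @param base base classifier, `"linear-svm"` or `"random-forest"`.
#' @param C linear cost parameter (the protocol with no parameter tuning:
#'   `C = 1`, `b_l = 0`).
#' @param n_trees forest size.
#' @param test_fraction fraction of documents held out for testing.
#' @param dev_fraction fraction of the training portion used as the dev set.
#' @param seed master seed; all stage seeds derive from it.
#' @return list of class `experiment_config`.
#' @export
experiment_config <- function(dataset = synthetic_spec(),
                              p_grid = c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6),
                              restorer = c("wknn", "softsl", "none"),
                              mode = c("add", "del", "none"),
                              k_grid = c(5, 10, 15, 20),
                              T_grid = c(0.05, 0.1, 0.15, 0.25, 0.3, 0.5),
                              mu = 0.5, softsl_T = 0.005,
                              base = c("linear-svm", "random-forest"),
                              C = 1, n_trees = 30,
                              test_fraction = 1 / 3, dev_fraction = 0.2,
                              seed = 1L) {
  restorer <- match.arg(restorer)
  mode <- match.arg(mode)
  base <- match.arg(base)
  stopifnot(length(k_grid) >= 1, length(T_grid) >= 1,
            all(p_grid >= 0), all(p_grid < 1),
            dev_fraction > 0, dev_fraction <= 0.5)
  if (restorer == "none") mode <- "none"
  structure(
    list(dataset = dataset, p_grid = sort(unique(p_grid)),
         restorer = restorer, mode = mode,
         k_grid = sort(unique(k_grid)), T_grid = sort(unique(T_grid)),
         mu = mu, softsl_T = softsl_T, base = base, C = C,
         n_trees = n_trees, test_fraction = test_fraction,
         dev_fraction = dev_fraction, seed = as.integer(seed)),
    class = "experiment_config"
  )
}

#' Run the corrupt / restore / modify / train / evaluate protocol
#'
#' For every deletion fraction `p` in the grid: the training labels are
#' corrupted with [delete_labels()]; if a restorer is configured, `(k, T)`
#' is chosen by grid search maximizing micro-F1 on the development split
#' (classifier fit on train-minus-dev, restoration votes drawn from
#' train-minus-dev only, ties broken toward smaller `k` then larger `T` —
#' fewer speculative additions); the winning configuration is re-run on the
#' whole training portion, the classifier retrained on the modified set,
#' and micro precision / recall / F1 measured on the untouched test set
#' with complete labels. A `p = 0` reference row (clean training set, no
#' modification) is always included.
#'
#' @param config an [experiment_config()].
#' @param verbose print progress messages.
#' @return tibble of class `ml_experiment` with one row per `p`:
#'   `p`, `restorer`, `mode`, `k_star`, `T_star`, `n_proposed`,
#'   `precision`, `recall`, `f1`, `dev_f1`. The configuration and split
#'   sizes are attached as attributes `"config"` and `"sizes"`.
#' @examples
#' \donttest{
#' cfg <- experiment_config(synthetic_spec(n_docs = 200, seed = 2),
#'                          p_grid = 0.4, k_grid = 10, T_grid = c(0.1, 0.3),
#'                          seed = 2)
#' run_experiment(cfg)
#' }
#' @export
run_experiment <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  ds <- config$dataset
  if (inherits(ds, "synthetic_spec")) ds <- generate_multilabel(ds)
  stopifnot(inherits(ds, "multilabel_dataset"))
  say <- function(...) if (verbose) message(...)
  split <- split_dataset(nrow(ds$X), config$test_fraction,
                         config$dev_fraction, seed = config$seed)
  train_port <- sort(c(split$train, split$dev))
  ds_trainport <- subset_dataset(ds, train_port)
  ds_test <- subset_dataset(ds, split$test, role = "test")
  # positions of the dev / train-minus-dev docs inside the training portion
  dev_rel <- match(split$dev, train_port)
  fit_rel <- match(split$train, train_port)

  eval_arm <- function(Y_corrupt, p, p_seed) {
    if (config$restorer == "none") {
      model <- train_br(ds_trainport$X, Y_corrupt, base = config$base,
                        C = config$C, n_trees = config$n_trees,
                        seed = p_seed)
      met <- micro_prf(ds_test$Y, predict(model, ds_test$X))
      return(tibble::tibble(k_star = NA_integer_, T_star = NA_real_,
                            n_proposed = 0L, dev_f1 = NA_real_, met))
    }
    # ---- grid search on the dev split (corrupted labels only) ----
    grid <- if (config$restorer == "wknn") {
      tidyr::expand_grid(k = config$k_grid, T = config$T_grid)
    } else {
      tidyr::expand_grid(k = config$k_grid, T = config$softsl_T)
    }
    best <- NULL
    for (k in unique(grid$k)) {
      graph_dev <- build_graph(ds_trainport$X, k, candidates = fit_rel)
      scores <- if (config$restorer == "wknn") {
        wknn_score_matrix(graph_dev, Y_corrupt)
      } else {
        NULL
      }
      # descending T so that on ties the larger threshold (fewer
      # speculative additions) is kept
      for (T in sort(grid$T[grid$k == k], decreasing = TRUE)) {
        pairs <- if (config$restorer == "wknn") {
          pairs_from_scores(scores, Y_corrupt, T)
        } else {
          restore_softsl(ds_trainport$X, Y_corrupt,
                         softsl_params(k = k, mu = config$mu, T = T),
                         graph = graph_dev)
        }
        fit_pairs <- dplyr::filter(pairs, .data$doc %in% fit_rel)
        dev_met <- fit_and_eval(
          ds_trainport, Y_corrupt, fit_pairs, fit_rel, dev_rel,
          config, p_seed)
        if (is.null(best) || dev_met$f1 > best$dev_f1 + 1e-12) {
          best <- list(k = k, T = T, dev_f1 = dev_met$f1)
        }
        say(sprintf("  p=%.1f k=%d T=%.3f dev_f1=%.4f", p, k, T, dev_met$f1))
      }
    }
    # ---- final fit on the whole training portion with (k*, T*) ----
    graph_full <- build_graph(ds_trainport$X, best$k)
    pairs <- if (config$restorer == "wknn") {
      restore_wknn(ds_trainport$X, Y_corrupt, T = best$T, graph = graph_full)
    } else {
      restore_softsl(ds_trainport$X, Y_corrupt,
                     softsl_params(k = best$k, mu = config$mu, T = best$T),
                     graph = graph_full)
    }
    Y_mod <- Y_corrupt
    mask <- NULL
    if (config$mode == "add") {
      Y_mod <- apply_add(Y_corrupt, pairs)
    } else if (config$mode == "del") {
      mask <- apply_del(Y_corrupt, pairs)
    }
    model <- train_br(ds_trainport$X, Y_mod, mask = mask, base = config$base,
                      C = config$C, n_trees = config$n_trees, seed = p_seed)
    met <- micro_prf(ds_test$Y, predict(model, ds_test$X))
    tibble::tibble(k_star = as.integer(best$k), T_star = best$T,
                   n_proposed = nrow(pairs), dev_f1 = best$dev_f1, met)
  }

  rows <- list()
  # p = 0 reference: clean labels, no modification
  say("p = 0 reference (clean training set)")
  model0 <- train_br(ds_trainport, base = config$base, C = config$C,
                     n_trees = config$n_trees, seed = config$seed)
  met0 <- micro_prf(ds_test$Y, predict(model0, ds_test$X))
  rows[[1]] <- tibble::tibble(
    p = 0, restorer = "none", mode = "none",
    k_star = NA_integer_, T_star = NA_real_, n_proposed = 0L,
    dev_f1 = NA_real_, met0)
  for (i in seq_along(config$p_grid)) {
    p <- config$p_grid[i]
    p_seed <- config$seed + 1000L * i
    say(sprintf("p = %.2f (%s+%s)", p, config$mode, config$restorer))
    corr <- delete_labels(ds_trainport$Y, p, seed = p_seed)
    arm <- eval_arm(corr$Y_incomplete, p, p_seed)
    rows[[i + 1]] <- tibble::tibble(
      p = p, restorer = config$restorer, mode = config$mode, arm)
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "config") <- config
  attr(out, "sizes") <- c(train = length(split$train),
                          dev = length(split$dev),
                          test = length(split$test))
  class(out) <- c("ml_experiment", class(out))
  out
}

# threshold previously computed score matrix into unlabeled proposals
pairs_from_scores <- function(S, Y, T) {
  keep <- which(S >= T & as.matrix(Y) == 0, arr.ind = TRUE)
  pairs <- tibble::tibble(doc = as.integer(keep[, 1]),
                          label = as.integer(keep[, 2]),
                          score = S[keep])
  class(pairs) <- c("relevance_pairs", class(pairs))
  pairs
}

# train on the fit split (pairs restricted to it), evaluate micro metrics
# on the dev split against its (corrupted) labels
fit_and_eval <- function(ds_trainport, Y_corrupt, fit_pairs, fit_rel,
                         dev_rel, config, seed) {
  Y_fit <- Y_corrupt[fit_rel, , drop = FALSE]
  local_pairs <- fit_pairs
  local_pairs$doc <- match(fit_pairs$doc, fit_rel)
  mask <- NULL
  if (config$mode == "add") {
    Y_fit <- apply_add(Y_fit, local_pairs)
  } else if (config$mode == "del") {
    mask <- apply_del(Y_fit, local_pairs)
  }
  model <- train_br(ds_trainport$X[fit_rel, , drop = FALSE], Y_fit,
                    mask = mask, base = config$base, C = config$C,
                    n_trees = config$n_trees, seed = seed)
  pred <- predict(model, ds_trainport$X[dev_rel, , drop = FALSE])
  micro_prf(Y_corrupt[dev_rel, , drop = FALSE], pred)
}

#' @rdname run_experiment
#' @param object an `ml_experiment` result.
#' @param ... unused.
#' @export
autoplot.ml_experiment <- function(object, ...) {
  df <- tidyr::pivot_longer(
    dplyr::mutate(object, arm = paste(.data$mode, .data$restorer, sep = "+")),
    cols = c("precision", "recall", "f1"),
    names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$p, y = .data$value,
                                   colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~arm) +
    ggplot2::labs(x = "fraction of deleted labels (p)", y = NULL,
                  title = "Test-set micro metrics vs label deletion") +
    ggplot2::ylim(0, 1)
}
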