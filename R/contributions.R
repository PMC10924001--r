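#' Additive per-feature attributions for an Extra Trees model
#'
#' Decomposes every prediction of a fitted tree ensemble into a base value
#' (the ensemble-average training mean) plus one additive contribution per
#' feature, in the tree-path-dependent fashion used for tree ensembles:
#' within each tree, a row is routed from the root to its leaf and the
#' change in the node's training mean at each split is credited to the
#' split feature; contributions are then averaged over trees. By
#' construction `base + rowSums(phi)` reconstructs the ensemble prediction
#' exactly (up to floating-point error), which is asserted internally at
#' 1e-6.
#'
#' @param model A `recomb_model` from [fit_recomb_model()].
#' @param newdata Rows to attribute (default: the model's training rows).
#' @return Object of class `recomb_contributions`: a list with
#'   \describe{
#'     \item{phi}{tibble of per-row attributions, one column per feature;}
#'     \item{base}{scalar base value;}
#'     \item{prediction}{ensemble predictions for the attributed rows;}
#'     \item{ranking}{tibble `feature`, `mean_abs`, `share` sorted by mean
#'       absolute attribution.}
#'   }
#' @examples
#' \donttest{
#' spec <- landscape_spec(chrom_length = 1e6, window_size = 1e5,
#'                        total_cM = 10, cg_base = 60, chg_base = 40,
#'                        chh_base = 20, seed = 9)
#' sim <- simulate_methylome(spec)
#' rt <- sim$truth; rt$rate[nrow(rt)] <- NA
#' ct <- build_consensus(sim$expected_windows, rt)
#' m <- fit_recomb_model(ct, seed = 1)
#' feature_contributions(m)$ranking
#' }
#' @export
feature_contributions <- function(model, newdata = NULL) {
  if (!inherits(model, "recomb_model")) {
    stop_invalid("feature attributions require a fitted `recomb_model`")
  }
  newdata <- newdata %||% model$train
  assert_columns(newdata, model$features, "attribution data")
  x <- as.matrix(as.data.frame(newdata[model$features]))
  fit <- model$fit
  p <- length(model$features)
  n <- nrow(x)

  train_x <- as.data.frame(model$train)
  terminal <- predict(fit, data = train_x, type = "terminalNodes",
                      num.threads = 1)$predictions

  phi <- matrix(0, nrow = n, ncol = p,
                dimnames = list(NULL, model$features))
  base <- 0
  pred_sum <- numeric(n)

  for (t in seq_len(fit$num.trees)) {
    info <- ranger::treeInfo(fit, t)
    info <- info[order(info$nodeID), , drop = FALSE]
    nv <- tree_node_values(info, terminal[, t])
    left <- info$leftChild
    right <- info$rightChild
    splitvar <- info$splitvarID + 1L   # 0-based in ranger
    splitval <- info$splitval
    is_term <- info$terminal

    base <- base + nv[1L]
    cur <- rep(1L, n)                  # nodeID 0 -> index 1
    active <- which(!is_term[cur])
    while (length(active) > 0L) {
      node <- cur[active]
      v <- splitvar[node]
      go_left <- x[cbind(active, v)] <= splitval[node]
      child <- ifelse(go_left, left[node], right[node]) + 1L
      delta <- nv[child] - nv[node]
      idx <- cbind(active, v)
      phi[idx] <- phi[idx] + delta
      cur[active] <- child
      active <- active[!is_term[child]]
    }
    pred_sum <- pred_sum + nv[cur]
  }

  phi <- phi / fit$num.trees
  base <- base / fit$num.trees
  prediction <- pred_sum / fit$num.trees

  resid <- abs(base + rowSums(phi) - prediction)
  if (max(resid) > 1e-6) {
    stop_compute(sprintf(
      "attribution additivity violated (max residual %.3g)", max(resid)))
  }

  mean_abs <- colMeans(abs(phi))
  ranking <- tibble(
    feature = model$features,
    mean_abs = unname(mean_abs),
    share = if (sum(mean_abs) > 0) unname(mean_abs / sum(mean_abs))
            else rep(0, p)
  )
  ranking <- ranking[order(-ranking$mean_abs), , drop = FALSE]

  structure(
    list(phi = as_tibble(as.data.frame(phi)), base = base,
         prediction = prediction, ranking = ranking),
    class = "recomb_contributions"
  )
}

# Training-mean value of every node of one tree: terminal values are
# ranger's leaf predictions; internal values are child means weighted by
# training occupancy. Children always have larger nodeIDs than parents, so
# a single reverse sweep suffices.
tree_node_values <- function(info, terminal_assignment) {
  n_nodes <- nrow(info)
  value <- numeric(n_nodes)
  count <- numeric(n_nodes)

  leaf_counts <- tabulate(terminal_assignment + 1L, nbins = n_nodes)
  term_idx <- which(info$terminal)
  value[term_idx] <- info$prediction[term_idx]
  count[term_idx] <- leaf_counts[term_idx]

  for (i in rev(which(!info$terminal))) {
    l <- info$leftChild[i] + 1L
    r <- info$rightChild[i] + 1L
    count[i] <- count[l] + count[r]
    if (count[i] > 0) {
      value[i] <- (value[l] * count[l] + value[r] * count[r]) / count[i]
    }
  }
  value
}

#' @export
print.recomb_contributions <- function(x, ...) {
  cat("<recomb_contributions>\n")
  cat(sprintf("  %d rows attributed; base value %.4g\n", nrow(x$phi), x$base))
  print(x$ranking)
  invisible(x)
}
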