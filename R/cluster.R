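#' Hierarchical density-based clustering with noise (HDBSCAN)
#'
#' A compact implementation of the HDBSCAN* algorithm suitable for the small
#' 2-D embeddings produced by [embed_cluster()]: core distances at
#' `min_samples`, the mutual-reachability minimum spanning tree, single
#' linkage, tree condensation at `min_cluster_size`, and excess-of-mass
#' cluster extraction. Low-density points receive the noise label `-1`.
#'
#' @param X Numeric matrix (observations x coordinates).
#' @param min_cluster_size Smallest component kept as a cluster (default 8).
#' @param min_samples Neighbour count defining the core distance (default 3;
#'   the point itself counts, as in the reference implementation).
#' @return Integer labels, `1..k` for clusters and `-1` for noise.
#' @export
hdbscan_labels <- function(X, min_cluster_size = 8, min_samples = 3) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < min_cluster_size) return(rep(-1L, n))
  D <- as.matrix(dist(X))
  core <- apply(D, 1, function(r) sort(r, partial = min_samples)[min_samples])
  mreach <- pmax(D, outer(core, core, pmax))
  diag(mreach) <- 0

  # Prim's MST on the mutual reachability graph
  in_tree <- rep(FALSE, n); in_tree[1] <- TRUE
  best_w <- mreach[1, ]; best_from <- rep(1L, n)
  edges <- matrix(0, n - 1, 3)
  for (e in seq_len(n - 1)) {
    cand <- which(!in_tree)
    j <- cand[which.min(best_w[cand])]
    edges[e, ] <- c(best_from[j], j, best_w[j])
    in_tree[j] <- TRUE
    upd <- !in_tree & mreach[j, ] < best_w
    best_from[upd] <- j
    best_w[upd] <- mreach[j, upd]
  }
  edges <- edges[order(edges[, 3]), , drop = FALSE]

  # single-linkage dendrogram over the MST edges
  parent_uf <- seq_len(2 * n - 1)
  find <- function(i) {
    while (parent_uf[i] != i) i <- parent_uf[i]
    i
  }
  node_of <- seq_len(n)             # uf root -> dendrogram node id
  children <- vector("list", 2 * n - 1)
  height <- numeric(2 * n - 1)
  pts <- c(as.list(seq_len(n)), vector("list", n - 1))
  nxt <- n
  for (e in seq_len(nrow(edges))) {
    ra <- find(edges[e, 1]); rb <- find(edges[e, 2])
    na_ <- node_of[ra]; nb <- node_of[rb]
    nxt <- nxt + 1L
    children[[nxt]] <- c(na_, nb)
    height[nxt] <- edges[e, 3]
    pts[[nxt]] <- c(pts[[na_]], pts[[nb]])
    parent_uf[ra] <- rb
    node_of[rb] <- nxt
  }
  root <- 2L * n - 1L

  lambda_of <- function(h) if (h <= 0) 1e12 else 1 / h

  # condense: clusters born at splits where both components keep
  # >= min_cluster_size points; smaller components fall out as points
  cl_parent <- integer(0); cl_birth <- numeric(0); cl_children <- list()
  pt_cluster <- integer(n); pt_lambda <- numeric(n)
  new_cluster <- function(parent, birth) {
    cl_parent[[length(cl_parent) + 1]] <<- parent
    cl_birth[[length(cl_birth) + 1]] <<- birth
    cl_children[[length(cl_parent)]] <<- integer(0)
    id <- length(cl_parent)
    if (parent > 0) cl_children[[parent]] <<- c(cl_children[[parent]], id)
    id
  }
  root_cl <- new_cluster(0L, 0)
  stack <- list(list(node = root, cl = root_cl))
  while (length(stack) > 0) {
    fr <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    node <- fr$node; cl <- fr$cl
    repeat {
      if (node <= n) { # singleton left as its own "cluster" point
        pt_cluster[node] <- cl
        pt_lambda[node] <- 1e12
        break
      }
      ch <- children[[node]]
      lam <- lambda_of(height[node])
      sz <- lengths(pts[ch])
      big <- sz >= min_cluster_size
      if (all(big)) {
        for (c2 in ch) {
          stack[[length(stack) + 1]] <- list(
            node = c2, cl = new_cluster(cl, lam)
          )
        }
        break
      } else if (any(big)) {
        small <- ch[!big]
        for (s in small) {
          pt_cluster[pts[[s]]] <- cl
          pt_lambda[pts[[s]]] <- lam
        }
        node <- ch[big][1]
      } else {
        for (c2 in ch) {
          pt_cluster[pts[[c2]]] <- cl
          pt_lambda[pts[[c2]]] <- lam
        }
        break
      }
    }
  }

  ncl <- length(cl_parent)
  if (ncl == 1) return(rep(-1L, n))   # no split survived condensation

  stability <- numeric(ncl)
  for (p in seq_len(n)) {
    c_ <- pt_cluster[p]
    stability[c_] <- stability[c_] + (pt_lambda[p] - cl_birth[c_])
  }
  cl_size <- tabulate(pt_cluster, ncl)
  # accumulate subtree point counts and split contributions
  for (c_ in rev(seq_len(ncl))) {
    if (cl_parent[c_] > 0) {
      p_ <- cl_parent[c_]
      stability[p_] <- stability[p_] +
        cl_size[c_] * (cl_birth[c_] - cl_birth[p_])
      cl_size[p_] <- cl_size[p_] + cl_size[c_]
    }
  }

  # excess-of-mass selection (root excluded)
  selected <- rep(FALSE, ncl)
  subtree_stab <- numeric(ncl)
  for (c_ in rev(seq_len(ncl))) {
    ch <- cl_children[[c_]]
    if (length(ch) == 0) {
      selected[c_] <- c_ != root_cl
      subtree_stab[c_] <- stability[c_]
    } else {
      s_child <- sum(subtree_stab[ch])
      if (c_ != root_cl && stability[c_] > s_child) {
        # deselect the whole subtree below c_
        stack2 <- ch
        while (length(stack2) > 0) {
          d <- stack2[[1]]; stack2 <- stack2[-1]
          selected[d] <- FALSE
          stack2 <- c(stack2, cl_children[[d]])
        }
        selected[c_] <- TRUE
        subtree_stab[c_] <- stability[c_]
      } else {
        subtree_stab[c_] <- s_child
      }
    }
  }

  labels <- rep(-1L, n)
  sel_ids <- which(selected)
  if (length(sel_ids) > 0) {
    remap <- setNames(seq_along(sel_ids), sel_ids)
    for (p in seq_len(n)) {
      c_ <- pt_cluster[p]
      while (c_ > 0 && !selected[c_]) c_ <- cl_parent[c_]
      if (c_ > 0) labels[p] <- remap[[as.character(c_)]]
    }
  }
  labels
}

#' Embed phenotype trajectories and cluster them
#'
#' Reduces the trajectory matrix to 2-D with UMAP (seeded, single-threaded,
#' hence deterministic) and clusters the embedding with HDBSCAN. Plants in
#' low-density regions keep the noise label `-1`.
#'
#' @param matrix Trajectory matrix from [build_trajectory_matrix()].
#' @param n_neighbors,min_dist UMAP parameters (defaults 5 and 0.05).
#' @param min_cluster_size,min_samples HDBSCAN parameters (defaults 8 and 3).
#' @param seed Integer seed.
#' @param plants Optional plant tibble (`plant_id`, `dose_uM`) used to attach
#'   per-cluster dose summaries.
#' @return A tibble of class `pl_clusters`: `plant_id`, `umap1`, `umap2`,
#'   `cluster`; attribute `cluster_summary` holds per-cluster size and dose
#'   mean/sd when `plants` is given.
#' @export
embed_cluster <- function(matrix, n_neighbors = 5, min_dist = 0.05,
                          min_cluster_size = 8, min_samples = 3,
                          seed = 1L, plants = NULL) {
  n <- nrow(matrix)
  if (n < min_cluster_size) {
    warning("fewer rows than min_cluster_size: all plants labelled noise")
    out <- tibble::tibble(
      plant_id = rownames(matrix) %||% as.character(seq_len(n)),
      umap1 = NA_real_, umap2 = NA_real_, cluster = -1L
    )
    class(out) <- c("pl_clusters", class(out))
    return(out)
  }
  emb <- withr::with_seed(as.integer(seed), {
    uwot::umap(matrix, n_neighbors = min(n_neighbors, n - 1),
               min_dist = min_dist, n_threads = 1, n_sgd_threads = 0)
  })
  labels <- hdbscan_labels(emb, min_cluster_size, min_samples)
  out <- tibble::tibble(
    plant_id = rownames(matrix) %||% as.character(seq_len(n)),
    umap1 = emb[, 1], umap2 = emb[, 2], cluster = labels
  )
  if (!is.null(plants)) {
    summ <- out %>%
      dplyr::filter(.data$cluster != -1) %>%
      dplyr::inner_join(plants[, c("plant_id", "dose_uM")], by = "plant_id") %>%
      dplyr::group_by(.data$cluster) %>%
      dplyr::summarise(
        n = dplyr::n(), dose_mean = mean(.data$dose_uM),
        dose_sd = sd(.data$dose_uM), .groups = "drop"
      ) %>%
      dplyr::arrange(.data$dose_mean)
    attr(out, "cluster_summary") <- summ
  }
  class(out) <- c("pl_clusters", class(out))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Statistics across trajectory clusters
#'
#' One-way ANOVA plus Tukey HSD across the non-noise clusters for dose and
#' for each supplied final-day feature.
#'
#' @param clusters A `pl_clusters` tibble from [embed_cluster()].
#' @param plants Plant tibble with `plant_id`, `dose_uM`.
#' @param daily Optional daily tibble; when given, the final-day value of
#'   each feature is compared across clusters as well.
#' @param final_day Day used for the feature comparison (default 25).
#' @return A tibble: `metric`, `pair`, `diff`, `p_adj`, plus attribute
#'   `anova_p` (named per metric).
#' @export
cluster_statistics <- function(clusters, plants, daily = NULL,
                               final_day = 25) {
  keep <- clusters$cluster != -1
  cl <- clusters[keep, ]
  if (length(unique(cl$cluster)) < 2) {
    stop("cluster_statistics: need >= 2 non-noise clusters", call. = FALSE)
  }
  metrics <- list(
    dose_uM = dplyr::inner_join(cl, plants[, c("plant_id", "dose_uM")],
                                by = "plant_id") %>%
      dplyr::select(cluster = "cluster", value = "dose_uM")
  )
  if (!is.null(daily)) {
    fin <- daily %>% dplyr::filter(.data$day == final_day)
    for (f in unique(fin$feature)) {
      metrics[[paste0(f, "_final")]] <- cl %>%
        dplyr::inner_join(fin[fin$feature == f, c("plant_id", "value")],
                          by = "plant_id") %>%
        dplyr::select(cluster = "cluster", value = "value")
    }
  }
  anova_p <- numeric(0)
  rows <- purrr::imap(metrics, function(df, metric) {
    gf <- factor(df$cluster)
    fit <- aov(df$value ~ gf)
    anova_p[[metric]] <<- summary(fit)[[1]][["Pr(>F)"]][1]
    tk <- TukeyHSD(fit)$gf
    tibble::tibble(
      metric = metric, pair = rownames(tk),
      diff = unname(tk[, "diff"]), p_adj = unname(tk[, "p adj"])
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "anova_p") <- anova_p
  out
}
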