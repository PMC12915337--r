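#' Pairwise Spearman correlation matrix with p-values
#'
#' Spearman rank correlations over all column pairs of a variables
#' table, using pairwise-complete observations and average ranks for
#' ties. Two-sided p-values come from the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of
#' freedom, with the pairwise `n`. Pairs involving a constant variable
#' (or fewer than 4 complete pairs) are undefined and returned as `NA`.
#'
#' @param table data frame of numeric variables (rows = time bins);
#'   non-numeric columns are dropped with a message.
#' @param min_pairs minimum complete pairs per tested pair (default 4).
#' @return list with matrices `rho`, `p`, `n`.
#' @export
spearman_matrix <- function(table, min_pairs = 4) {
  tab <- as_tibble(table)
  num <- vapply(tab, is.numeric, logical(1))
  if (any(!num)) {
    message("dropping non-numeric columns: ",
      paste(names(tab)[!num], collapse = ", ")
    )
    tab <- tab[num]
  }
  x <- as.matrix(tab)
  p_vars <- ncol(x)
  rho <- matrix(NA_real_, p_vars, p_vars,
    dimnames = list(colnames(x), colnames(x))
  )
  pmat <- rho
  nmat <- matrix(NA_integer_, p_vars, p_vars,
    dimnames = dimnames(rho)
  )
  for (i in seq_len(p_vars)) {
    for (j in i:p_vars) {
      ok <- stats::complete.cases(x[, i], x[, j])
      n <- sum(ok)
      nmat[i, j] <- nmat[j, i] <- n
      if (i == j) {
        rho[i, j] <- 1
        pmat[i, j] <- NA_real_
        next
      }
      if (n < min_pairs) next
      xi <- x[ok, i]
      xj <- x[ok, j]
      if (stats::sd(xi) == 0 || stats::sd(xj) == 0) next # constant: undefined
      r <- stats::cor(xi, xj, method = "spearman")
      rho[i, j] <- rho[j, i] <- r
      pmat[i, j] <- pmat[j, i] <- spearman_p(r, n)
    }
  }
  list(rho = rho, p = pmat, n = nmat)
}

# two-sided p from the t approximation to Spearman's rho
spearman_p <- function(r, n) {
  if (is.na(r) || n < 3) return(NA_real_)
  if (abs(r) >= 1) return(0)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
}

#' Prune collinear variables
#'
#' Greedy scan in column order: each variable is dropped if its absolute
#' Spearman correlation with an already-kept variable exceeds the
#' threshold, so near-duplicate measurements (dew point vs temperature,
#' and the like) enter the analysis only once.
#'
#' @param table data frame of numeric variables.
#' @param threshold absolute-correlation cutoff (default 0.8).
#' @param keep variables exempt from dropping (the study's focal
#'   variables: pruning is aimed at redundant environmental covariates,
#'   never at the quantities under study).
#' @return list with `kept` (character vector of retained columns) and
#'   `dropped` (tibble mapping each dropped variable to the kept
#'   variable that excluded it, with the offending `rho`).
#' @export
prune_collinear <- function(table, threshold = 0.8, keep = NULL) {
  sm <- suppressMessages(spearman_matrix(table, min_pairs = 3))
  vars <- colnames(sm$rho)
  kept <- intersect(keep, vars)
  dropped <- list()
  for (v in setdiff(vars, kept)) {
    r <- sm$rho[v, kept]
    hit <- which(!is.na(r) & abs(r) > threshold)
    if (length(hit)) {
      dropped[[v]] <- tibble(
        dropped = v, keeper = kept[hit[1]], rho = unname(r[hit[1]])
      )
    } else {
      kept <- c(kept, v)
    }
  }
  list(kept = kept, dropped = bind_rows(dropped))
}

#' Build a significance-filtered correlation network
#'
#' Keeps an undirected edge for every variable pair with `p < alpha`;
#' the edge sign is the sign of rho. Node classes (population, PM,
#' meteorology, pathway, metal, gas, other) tag what each variable
#' measures and travel into the exports.
#'
#' @param rho,p square matrices as from [spearman_matrix()].
#' @param alpha significance cutoff on the raw p-value (default 0.05;
#'   no multiplicity correction, matching common practice for these
#'   exploratory displays).
#' @param classes optional named character vector mapping node name to
#'   class; unnamed variables get `"other"`.
#' @return object of class `cor_network`: list with `nodes` (tibble
#'   `name`, `class`) and `edges` (tibble `from`, `to`, `rho`, `p`,
#'   `sign`).
#' @export
build_network <- function(rho, p, alpha = 0.05, classes = NULL) {
  stopifnot(identical(dim(rho), dim(p)), nrow(rho) == ncol(rho))
  vars <- colnames(rho)
  cls <- rep("other", length(vars))
  names(cls) <- vars
  if (!is.null(classes)) {
    hit <- intersect(names(classes), vars)
    cls[hit] <- classes[hit]
  }
  idx <- which(upper.tri(rho) & !is.na(p) & p < alpha, arr.ind = TRUE)
  rho_e <- rho[idx]
  p_e <- p[idx]
  edges <- tibble(
    from = vars[idx[, 1]],
    to = vars[idx[, 2]],
    rho = rho_e,
    p = p_e,
    sign = ifelse(rho_e >= 0, "positive", "negative")
  )
  structure(
    list(
      nodes = tibble(name = vars, class = unname(cls)),
      edges = edges,
      alpha = alpha
    ),
    class = "cor_network"
  )
}

#' @export
print.cor_network <- function(x, ...) {
  cat(sprintf(
    "Correlation network: %d nodes, %d edges (%d positive / %d negative), alpha = %g\n",
    nrow(x$nodes), nrow(x$edges),
    sum(x$edges$sign == "positive"), sum(x$edges$sign == "negative"),
    x$alpha
  ))
  invisible(x)
}

as_igraph_network <- function(net, positive_only = FALSE) {
  e <- net$edges
  if (positive_only) e <- e[e$sign == "positive", ]
  igraph::graph_from_data_frame(
    d = e, directed = FALSE,
    vertices = as.data.frame(net$nodes)
  )
}

#' Detect network modules
#'
#' Greedy modularity maximization (fast-greedy community detection) on
#' the positive-edge graph weighted by `|rho|`. Negative edges are kept
#' for display but excluded from community structure. Deterministic for
#' a fixed node ordering.
#'
#' @param net a `cor_network`.
#' @return tibble with `node` and integer `module` (nodes with no
#'   positive edges form singleton modules).
#' @export
find_modules <- function(net) {
  stopifnot(inherits(net, "cor_network"))
  if (nrow(net$nodes) == 0) stop("empty network", call. = FALSE)
  g <- as_igraph_network(net, positive_only = TRUE)
  if (igraph::ecount(g) > 0) {
    w <- abs(igraph::E(g)$rho)
    comm <- igraph::cluster_fast_greedy(g, weights = w)
    memb <- as.integer(igraph::membership(comm))
    names(memb) <- igraph::V(g)$name
    # deterministic post-pass: merge edge-connected modules whenever the
    # merge does not decrease modularity (the agglomeration above stops
    # at strictly positive gains, leaving e.g. a single edge split)
    ends <- igraph::ends(g, igraph::E(g))
    q_cur <- igraph::modularity(g, memb, weights = w)
    repeat {
      pairs <- unique(t(apply(
        cbind(memb[ends[, 1]], memb[ends[, 2]]), 1, sort
      )))
      pairs <- pairs[pairs[, 1] != pairs[, 2], , drop = FALSE]
      if (nrow(pairs) == 0) break
      merged <- FALSE
      for (r in seq_len(nrow(pairs))) {
        trial <- memb
        trial[trial == pairs[r, 2]] <- pairs[r, 1]
        q_new <- igraph::modularity(g, trial, weights = w)
        if (q_new >= q_cur - 1e-12) {
          memb <- trial
          q_cur <- q_new
          merged <- TRUE
          break
        }
      }
      if (!merged) break
    }
    memb <- match(memb, sort(unique(memb)))
    names(memb) <- igraph::V(g)$name
  } else {
    memb <- seq_len(igraph::vcount(g))
    names(memb) <- igraph::V(g)$name
  }
  tibble(node = names(memb), module = as.integer(memb))
}

#' Extract the subnetwork around focal nodes
#'
#' Keeps the focal nodes and their first neighbors, retaining only
#' edges with at least one focal endpoint; correlations among the
#' non-focal neighbors are dropped, so the display emphasises how the
#' environment connects to the focal variables.
#'
#' @param net a `cor_network`.
#' @param focal character vector of node names.
#' @return a `cor_network`.
#' @export
ego_subnetwork <- function(net, focal) {
  stopifnot(inherits(net, "cor_network"))
  unknown <- setdiff(focal, net$nodes$name)
  if (length(unknown)) {
    stop("unknown focal node(s): ", paste(unknown, collapse = ", "),
      call. = FALSE
    )
  }
  e <- net$edges
  touch <- e$from %in% focal | e$to %in% focal
  e <- e[touch, ]
  keep_nodes <- union(focal, union(e$from, e$to))
  structure(
    list(
      nodes = net$nodes[net$nodes$name %in% keep_nodes, ],
      edges = e,
      alpha = net$alpha
    ),
    class = "cor_network"
  )
}

#' Export a network in SIF format
#'
#' Simple interaction format: one `source <relation> target` line per
#' edge (relation `pos`/`neg`), plus isolated nodes on their own lines;
#' loadable by Cytoscape.
#'
#' @param net a `cor_network`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sif <- function(net, path) {
  stopifnot(inherits(net, "cor_network"))
  e <- net$edges
  lines <- sprintf(
    "%s\t%s\t%s", e$from, ifelse(e$sign == "positive", "pos", "neg"), e$to
  )
  isolated <- setdiff(net$nodes$name, union(e$from, e$to))
  writeLines(c(lines, isolated), path)
  invisible(path)
}

#' Export a network in GraphML format
#'
#' GraphML with the node `class` attribute and edge `rho`, `p` and
#' `sign` attributes, Cytoscape-compatible, via [igraph::write_graph()].
#'
#' @inheritParams write_sif
#' @export
write_graphml <- function(net, path) {
  stopifnot(inherits(net, "cor_network"))
  g <- as_igraph_network(net)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Export the network edge list as CSV
#'
#' @inheritParams write_sif
#' @export
write_edge_csv <- function(net, path) {
  stopifnot(inherits(net, "cor_network"))
  utils::write.csv(net$edges, path, row.names = FALSE)
  invisible(path)
}
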