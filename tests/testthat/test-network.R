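test_that("spearman matrix equals the rank-then-Pearson oracle", {
  set.seed(5)
  for (i in 1:6) {
    tab <- tibble::as_tibble(matrix(rnorm(25), 5, 5, dimnames = list(NULL, letters[1:5])))
    if (i %% 2 == 0) tab$b <- tab$a^3 # ties-free monotone pair
    sm <- spearman_matrix(tab)
    for (a in 1:4) {
      for (b in (a + 1):5) {
        expect_close(sm$rho[a, b], spearman_oracle(tab[[a]], tab[[b]]), 1e-12)
      }
    }
    expect_equal(sm$rho, t(sm$rho))
    expect_equal(unname(diag(sm$rho)), rep(1, 5))
    expect_true(all(abs(sm$rho) <= 1 + 1e-12))
  }
})

test_that("monotone transforms give |rho| = 1 and constants are undefined", {
  x <- c(0.5, 1.2, 2.5, 3.1, 4.8)
  sm <- spearman_matrix(tibble::tibble(x = x, y = x^2, z = -x, c = rep(1, 5)))
  expect_equal(sm$rho["x", "y"], 1)
  expect_equal(sm$rho["x", "z"], -1)
  expect_true(is.na(sm$rho["x", "c"]))
  # p-values follow the two-sided t approximation
  set.seed(8)
  a <- rnorm(20)
  b <- a + rnorm(20)
  sm2 <- spearman_matrix(tibble::tibble(a = a, b = b))
  r <- sm2$rho["a", "b"]
  tstat <- r * sqrt((20 - 2) / (1 - r^2))
  expect_close(sm2$p["a", "b"], 2 * pt(abs(tstat), 18, lower.tail = FALSE), 1e-12)
})

test_that("collinearity pruning drops near-duplicates in column order", {
  set.seed(2)
  n <- 36
  temperature <- rnorm(n)
  tab <- tibble::tibble(
    temperature = temperature,
    dew_point = temperature + rnorm(n, sd = 0.1), # rho > 0.8 by construction
    humidity = rnorm(n)
  )
  pr <- prune_collinear(tab, threshold = 0.8)
  expect_equal(pr$kept, c("temperature", "humidity"))
  expect_equal(pr$dropped$dropped, "dew_point")
  expect_equal(pr$dropped$keeper, "temperature")
  # exact duplicate column
  pr2 <- prune_collinear(tibble::tibble(a = temperature, b = temperature))
  expect_equal(pr2$kept, "a")
  # independent noise columns survive at n = 36
  set.seed(31)
  keep_all <- replicate(20, {
    tabi <- tibble::as_tibble(matrix(rnorm(36 * 5), 36, 5,
      dimnames = list(NULL, letters[1:5])
    ))
    length(prune_collinear(tabi)$kept)
  })
  expect_gte(mean(keep_all == 5), 0.9)
})

test_that("network keeps only significant edges with signs from rho", {
  rho <- matrix(c(1, .9, -.9, .9, 1, .1, -.9, .1, 1), 3, 3,
    dimnames = list(c("a", "b", "c"), c("a", "b", "c"))
  )
  p_all_1 <- matrix(1, 3, 3, dimnames = dimnames(rho))
  expect_equal(nrow(build_network(rho, p_all_1)$edges), 0)
  p_small <- matrix(0.001, 3, 3, dimnames = dimnames(rho))
  net <- build_network(rho, p_small, alpha = 1.01)
  expect_equal(nrow(net$edges), 3) # complete graph minus undefined pairs
  expect_equal(
    net$edges$sign[net$edges$from == "a" & net$edges$to == "c"], "negative"
  )
  expect_false(any(net$edges$from == net$edges$to))
})

test_that("modules separate disconnected components and co-assign coupled variables", {
  nodes <- letters[1:6]
  rho <- diag(6)
  dimnames(rho) <- list(nodes, nodes)
  p <- matrix(1, 6, 6, dimnames = dimnames(rho))
  tri <- function(i, j) {
    rho[i, j] <<- rho[j, i] <<- 0.9
    p[i, j] <<- p[j, i] <<- 0.001
  }
  tri(1, 2); tri(2, 3); tri(1, 3) # triangle 1
  tri(4, 5); tri(5, 6); tri(4, 6) # triangle 2
  net <- build_network(rho, p)
  mods <- find_modules(net)
  m <- mods$module[match(nodes, mods$node)]
  expect_equal(length(unique(m[1:3])), 1)
  expect_equal(length(unique(m[4:6])), 1)
  expect_false(m[1] == m[4])
  # a single edge is one module of two nodes
  rho2 <- diag(2)
  dimnames(rho2) <- list(c("x", "y"), c("x", "y"))
  rho2[1, 2] <- rho2[2, 1] <- 0.8
  p2 <- matrix(0.01, 2, 2, dimnames = dimnames(rho2))
  mods2 <- find_modules(build_network(rho2, p2))
  expect_equal(length(unique(mods2$module)), 1)
})

test_that("ego subnetwork keeps focal nodes, neighbors, and only focal-touching edges", {
  nodes <- c("hub", "a", "b", "c")
  rho <- diag(4)
  dimnames(rho) <- list(nodes, nodes)
  p <- matrix(1, 4, 4, dimnames = dimnames(rho))
  link <- function(i, j, r = 0.9) {
    rho[i, j] <<- rho[j, i] <<- r
    p[i, j] <<- p[j, i] <<- 0.001
  }
  link(1, 2); link(1, 3); link(2, 3); link(3, 4)
  net <- build_network(rho, p)
  ego <- ego_subnetwork(net, "hub")
  expect_setequal(ego$nodes$name, c("hub", "a", "b"))
  expect_true(all(ego$edges$from == "hub" | ego$edges$to == "hub"))
  # focal node with no edges -> singleton
  rho0 <- diag(2)
  dimnames(rho0) <- list(c("u", "v"), c("u", "v"))
  net0 <- build_network(rho0, matrix(1, 2, 2, dimnames = dimnames(rho0)))
  expect_equal(ego_subnetwork(net0, "u")$nodes$name, "u")
  expect_error(ego_subnetwork(net, "nope"), "unknown focal")
})

test_that("exports write SIF lines and loadable GraphML with attributes", {
  rho <- matrix(c(1, .9, .9, 1), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  p <- matrix(0.01, 2, 2, dimnames = dimnames(rho))
  net <- build_network(rho, p, classes = c(a = "population", b = "PM"))
  sif <- tempfile(fileext = ".sif")
  gml <- tempfile(fileext = ".graphml")
  csv <- tempfile(fileext = ".csv")
  write_sif(net, sif)
  write_graphml(net, gml)
  write_edge_csv(net, csv)
  expect_equal(readLines(sif), "a\tpos\tb")
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(g), 2)
  expect_equal(igraph::E(g)$rho, 0.9)
  expect_setequal(igraph::V(g)$class, c("population", "PM"))
  expect_equal(nrow(read.csv(csv)), 1)
})

test_that("a campaign-scale world groups the dust variables with negative humidity links", {
  rep <- suppressWarnings(run_full_analysis(seed = 2))
  mods <- rep$network$modules
  m <- mods$module[match(c("abundance", "local_pm10", "desert_pm10"), mods$node)]
  expect_equal(length(unique(m)), 1)
  # the focal subnetwork links the aerosol variables negatively to the
  # warm, humid summer conditions
  ego <- rep$network$ego
  met_edges <- ego$edges[ego$edges$from %in% c("humidity", "temperature") |
    ego$edges$to %in% c("humidity", "temperature"), ]
  expect_gt(nrow(met_edges), 0)
  expect_true(all(met_edges$sign == "negative"))
  # every retained edge is significant at the configured level
  expect_true(all(rep$network$net$edges$p < 0.05))
})
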