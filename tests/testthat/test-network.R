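test_that("network gene filter keeps genes with >=10 samples at value >=3", {
  m <- rbind(
    boundary = c(rep(3, 10), rep(0, 10)),       # exactly at both bounds
    below = c(rep(3, 9), rep(2.9, 11)),         # only 9 qualifying samples
    zero = rep(0, 20),
    high = rep(100, 20))
  colnames(m) <- paste0("s", 1:20)
  out <- filter_network_genes(m)
  expect_setequal(rownames(out), c("boundary", "high"))
})

test_that("TF expression filter is strict on the count threshold", {
  m <- rbind(
    kept = c(11, 11, 11, rep(0, 7)),
    removed = c(10, 10, 10, rep(0, 7)),
    other = rep(100, 10))
  colnames(m) <- paste0("s", 1:10)
  expect_identical(filter_expressed_tfs(m, c("kept", "removed")), "kept")
  expect_identical(filter_expressed_tfs(m, character()), character())
  expect_warning(out <- filter_expressed_tfs(m, c("kept", "ghost")),
                 "ghost")
  expect_identical(out, "kept")
})

test_that("an exact-copy target ranks its parent TF first with dominant
           importance", {
  set.seed(301)
  n_samples <- 60
  tfs <- sprintf("TF%02d", 1:31)
  expr <- matrix(rnorm(31 * n_samples, 5, 1), nrow = 31,
                 dimnames = list(tfs, paste0("s", 1:n_samples)))
  copy <- expr["TF07", ] + rnorm(n_samples, 0, 1e-3)
  expr <- rbind(expr, target = copy)
  net <- infer_network(expr, tfs, targets = "target", n_trees = 500, seed = 9)
  e <- net$edges
  expect_identical(e$tf[1], "TF07")
  # impurity importance is diluted by noise splits at mtry = sqrt(p); the
  # parent still dominates the runner-up by a wide margin
  expect_gt(e$importance[1], 2 * e$importance[2])
  # permutation importance concentrates the signal on the true parent
  pnet <- infer_network(expr, tfs, targets = "target", n_trees = 500,
                        importance = "permutation", seed = 9)
  pe <- pnet$edges
  expect_identical(pe$tf[1], "TF07")
  expect_gt(pe$importance[1] / sum(pe$importance), 0.5)
  # correlation oracle agrees on the winner
  cors <- abs(cor(t(expr[tfs, ]), copy))
  expect_identical(rownames(cors)[which.max(cors)], "TF07")
  # far more predictable out of bag than any noise target
  expect_gt(net$r2[["target"]], 0.3)
})

test_that("a target independent of all TFs has out-of-bag r2 near zero and a
           constant target yields zero importances", {
  set.seed(302)
  tfs <- sprintf("TF%02d", 1:20)
  expr <- matrix(rnorm(20 * 60, 5, 1), nrow = 20,
                 dimnames = list(tfs, paste0("s", 1:60)))
  expr <- rbind(expr,
                noise = rnorm(60, 5, 1),
                flat = rep(2, 60))
  net <- infer_network(expr, tfs, targets = c("noise", "flat"),
                       n_trees = 500, seed = 4)
  expect_lt(abs(net$r2[["noise"]]), 0.15)
  expect_equal(net$r2[["flat"]], 0)
  expect_true(all(net$edges$importance[net$edges$target == "flat"] == 0))
})

test_that("inference is invariant to the order of rows and of the TF list", {
  set.seed(303)
  tfs <- sprintf("TF%02d", 1:15)
  expr <- matrix(rnorm(15 * 50, 5, 1), nrow = 15,
                 dimnames = list(tfs, paste0("s", 1:50)))
  expr <- rbind(expr, tgt = expr["TF03", ] * 0.9 + rnorm(50, 0, 0.3))
  n1 <- infer_network(expr, tfs, targets = "tgt", n_trees = 300, seed = 7)
  perm <- sample(nrow(expr))
  n2 <- infer_network(expr[perm, ], rev(tfs), targets = "tgt",
                      n_trees = 300, seed = 7)
  expect_equal(n1$edges, n2$edges)
  expect_equal(n1$r2, n2$r2)
})

test_that("a TF is excluded from its own predictor set", {
  set.seed(304)
  tfs <- sprintf("TF%02d", 1:10)
  expr <- matrix(rnorm(10 * 40, 5, 1), nrow = 10,
                 dimnames = list(tfs, paste0("s", 1:40)))
  net <- infer_network(expr, tfs, targets = "TF01", n_trees = 100, seed = 2)
  expect_false("TF01" %in% net$edges$tf)
  expect_equal(nrow(net$edges), 9)
})

test_that("top-k thresholding keeps the k best edges with deterministic
           tie-breaks", {
  edges <- data.frame(
    tf = c(paste0("tf", 1:8), "tfA", "tfB", "tfC"),
    target = c(rep("t1", 8), rep("t2", 3)),
    importance = c(8:1, 0.5, 0.5, 0.5))
  net <- structure(list(edges = edges, r2 = c(t1 = 0.5, t2 = 0.1)),
                   class = "grn")
  top <- threshold_top_k(net, 5)
  e1 <- top$edges[top$edges$target == "t1", ]
  expect_equal(nrow(e1), 5)
  expect_setequal(e1$tf, paste0("tf", 1:5))
  # fewer candidates than k are all kept
  expect_equal(sum(top$edges$target == "t2"), 3)
  expect_error(threshold_top_k(net, 0), "k must be")

  # tie at the cutoff: lexicographically smaller TF id wins
  tie <- data.frame(tf = c("z", "a", "m", "b", "c", "d", "e"),
                    target = "t", importance = c(9, 9, 9, 9, 1, 1, 1))
  tnet <- structure(list(edges = tie, r2 = c(t = 0)), class = "grn")
  kept <- threshold_top_k(tnet, 5)$edges$tf
  expect_identical(kept, c("a", "b", "m", "z", "c"))

  # retained edges never exceed k per target
  b <- default_sim_bundle()
  expect_lte(max(table(threshold_top_k(structure(list(
    edges = data.frame(tf = rep(paste0("T", 1:12), 4),
                       target = rep(paste0("g", 1:4), each = 12),
                       importance = runif(48)), r2 = NULL),
    class = "grn"), 5)$edges$target)), 5)
})

test_that("hypoxia subgraph extraction applies the degree filter and is
           idempotent", {
  hyp <- paste0("h", 1:20)
  edges <- rbind(
    data.frame(tf = "tfBig", target = paste0("h", 1:10), importance = 1),
    data.frame(tf = "tfSmall", target = paste0("h", 1:9), importance = 1),
    data.frame(tf = "tfOff", target = paste0("x", 1:15), importance = 1))
  net <- structure(list(edges = edges,
                        r2 = stats::setNames(rep(0.5, 35),
                                             edges$target)),
                   class = "grn")
  sub <- extract_hypoxia_subgraph(net, hyp, min_degree = 10)
  expect_setequal(unique(sub$edges$tf), "tfBig") # 10 kept, 9 dropped
  expect_equal(nrow(sub$edges), 10)
  sub2 <- extract_hypoxia_subgraph(sub, hyp, min_degree = 10)
  expect_equal(sub$edges, sub2$edges)
  # empty hypoxia set gives an empty subgraph, not an error
  empty <- extract_hypoxia_subgraph(net, character())
  expect_equal(nrow(empty$edges), 0)
  # all edges already qualifying: subgraph equals input
  big <- structure(list(edges = edges[edges$tf == "tfBig", ],
                        r2 = NULL), class = "grn")
  expect_equal(extract_hypoxia_subgraph(big, hyp, 10)$edges,
               big$edges, ignore_attr = TRUE)
})

test_that("TF classification uses the normalized dividing line", {
  # on the line is not above it
  expect_identical(classify_tf(143, 24, 24 / 143), "standard")
  expect_identical(classify_tf(10, 5, 24 / 143), "ethylene_mediated")
  expect_identical(classify_tf(100, 0, 0.5), "standard")
  expect_error(classify_tf(1, 1, 0), "slope")

  # scale invariance: multiplying x, y and both maxima by c preserves labels
  set.seed(305)
  for (i in 1:100) {
    x <- sample(0:150, 10, replace = TRUE)
    y <- sample(0:30, 10, replace = TRUE)
    cc <- runif(1, 0.1, 9)
    base <- classify_tfs(data.frame(tf = paste0("t", 1:10), x = x, y = y))
    scaled <- classify_tfs(data.frame(tf = paste0("t", 1:10),
                                      x = cc * x, y = cc * y))
    expect_identical(base$label, scaled$label)
  }

  # degenerate case: no TF targets any standard-hypoxia gene
  deg <- classify_tfs(data.frame(tf = c("a", "b"), x = c(0, 0), y = c(2, 0)))
  expect_identical(deg$label, c("ethylene_mediated", "standard"))
})

test_that("per-TF target counts split the hypoxia set into compartments", {
  edges <- data.frame(tf = c("t1", "t1", "t1", "t2"),
                      target = c("h1", "h2", "e1", "x1"),
                      importance = 1)
  net <- structure(list(edges = edges, r2 = NULL), class = "grn")
  counts <- tf_target_counts(net, hypoxia_all = c("h1", "h2", "e1"),
                             ethylene_subsets = "e1")
  expect_equal(counts$x[counts$tf == "t1"], 2)
  expect_equal(counts$y[counts$tf == "t1"], 1)
  expect_equal(counts$x[counts$tf == "t2"], 0)
})

test_that("focal-TF subnetwork reports pairwise and all-focal overlaps", {
  pool <- function(tf, targets) data.frame(tf = tf, target = targets,
                                           importance = 1)
  shared <- paste0("s", 1:5)
  edges <- rbind(pool("A", c(shared, paste0("a", 1:3))),
                 pool("B", c(shared, paste0("b", 1:4))),
                 pool("C", c(shared, paste0("c", 1:2))),
                 pool("D", paste0("d", 1:6)))
  net <- structure(list(edges = edges, r2 = NULL), class = "grn")
  sub <- focal_tf_subnetwork(net, c("A", "B", "C"), annotate_set = shared)
  expect_equal(sub$intersection_all, sort(shared))
  ov <- sub$overlap
  expect_equal(ov$overlap[ov$tf1 == "A" & ov$tf2 == "B"], 5)
  expect_true(all(sub$targets$annotated[sub$targets$target %in% shared]))
  expect_false("D" %in% sub$edges$tf)
  # disjoint pools: zero overlap
  sub2 <- focal_tf_subnetwork(net, c("A", "D"))
  expect_equal(sub2$overlap$overlap, 0)
  expect_error(focal_tf_subnetwork(net, "ZZ"), "not TFs")
})
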