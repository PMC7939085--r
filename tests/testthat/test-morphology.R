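test_that("default morphology has the canonical branch/limb structure", {
  sec <- build_reduced_pc()
  expect_equal(sum(is.na(sec$parent_id)), 1L)     # one root: the soma
  expect_setequal(unique(na.omit(sec$branch_id)), 1:22)
  expect_setequal(unique(na.omit(sec$limb_id)), 1:3)
  # branches 1-8 left, 9-13 middle, 14-22 right
  bl <- unique(sec[!is.na(sec$branch_id), c("branch_id", "limb_id")])
  expect_equal(bl$limb_id[match(1:22, bl$branch_id)],
               c(rep(1L, 8), rep(2L, 5), rep(3L, 9)))
})

test_that("branch areas match the configured schedule by construction", {
  g <- canonical_model()$graph
  bg <- branch_geometry_summary(g)
  cfg <- morphology_config()
  expect_equal(nrow(bg), 22L)
  expect_lt(max(abs(bg$area_um2 / cfg$branches$area_um2 - 1)), 1e-3)
})

test_that("exactly one compartment connects each branch to the main dendrite", {
  g <- canonical_model()$graph
  for (b in as.character(1:22)) {
    members <- g$branch_index[[b]]
    parents <- g$comps$parent[members]
    outside <- setdiff(parents, c(members, 0L))
    expect_length(outside, 1L)                      # a single entry point
    expect_equal(g$comps$region[outside], "main")
    conn <- g$connection_segment[[b]]
    expect_equal(g$comps$parent[conn], outside)
  }
})

test_that("invalid branch schedules are rejected", {
  cfg <- morphology_config()
  cfg$branches <- cfg$branches[-1, ]                # 21 branches
  expect_error(build_reduced_pc(cfg), "22")
  cfg2 <- morphology_config()
  cfg2$branches$area_um2[3] <- -10
  expect_error(build_reduced_pc(cfg2), "positive")
})

test_that("cylindrical axial resistance matches the closed form", {
  # 4*rho*L/(pi*d^2): 50 um, 1 um, 120 Ohm cm -> 76.4 MOhm
  expect_equal(cylinder_axial_resistance(50, 1, 120), 76.39437, tolerance = 1e-5)
})

test_that("splitting a section conserves end-to-end axial resistance", {
  full <- cylinder_axial_resistance(80, 1.2, 120)
  for (n in c(2, 5, 8)) {
    g <- toy_chain(n, len = 80 / n, diam = 1.2)
    internal <- axial_path_resistance(g, 1, n)
    # add the two half-segments beyond the end compartment centres
    ends <- 2 * cylinder_axial_resistance(80 / n / 2, 1.2, 120)
    expect_equal(internal + ends, full, tolerance = 1e-6)
  }
})

test_that("discretization overrides set compartment counts per section", {
  sec <- build_reduced_pc()
  tipsec <- sec$id[!is.na(sec$kind) & sec$kind == "tip"][1]
  g <- discretize(sec, rule = list(max_len = 25,
                                   overrides = setNames(3L, tipsec)))
  expect_equal(sum(g$comps$section_id == tipsec), 3L)
  expect_error(discretize(sec, rule = list(max_len = 25,
                                           overrides = c(nosuch = 3L))),
               "unknown section")
})

test_that("axial path resistance agrees with a brute-force graph search", {
  g <- canonical_model()$graph
  # independent oracle: undirected adjacency + breadth-first path search
  adj <- lapply(seq_len(g$n), function(i) integer())
  w <- list()
  for (i in seq_len(g$n)) {
    p <- g$comps$parent[i]
    if (p > 0) {
      adj[[i]] <- c(adj[[i]], p)
      adj[[p]] <- c(adj[[p]], i)
    }
  }
  edge_w <- function(a, b) {
    if (g$comps$parent[a] == b) g$comps$ra[a] else g$comps$ra[b]
  }
  bfs_resistance <- function(from, to) {
    prev <- rep(NA_integer_, g$n)
    prev[from] <- from
    queue <- from
    while (length(queue)) {
      x <- queue[1]; queue <- queue[-1]
      if (x == to) break
      for (nb in adj[[x]]) if (is.na(prev[nb])) {
        prev[nb] <- x
        queue <- c(queue, nb)
      }
    }
    r <- 0; x <- to
    while (x != from) { r <- r + edge_w(x, prev[x]); x <- prev[x] }
    r
  }
  set.seed(42)
  pairs <- cbind(sample(g$n, 8), sample(g$n, 8))
  for (k in seq_len(nrow(pairs))) {
    a <- pairs[k, 1]; b <- pairs[k, 2]
    expect_equal(axial_path_resistance(g, a, b), bfs_resistance(a, b),
                 tolerance = 1e-9)
    expect_equal(axial_path_resistance(g, a, b),
                 axial_path_resistance(g, b, a))
  }
  expect_equal(axial_path_resistance(g, 5, 5), 0)
})

test_that("tree structure and ordering invariants hold on every build", {
  g <- canonical_model()$graph
  expect_equal(sum(g$comps$parent == 0L), 1L)
  expect_true(all(g$comps$parent < g$comps$id))    # parent-before-child
  # total membrane area equals the section-level sum
  sec_area <- sum(pi * g$sections$diam * g$sections$length)
  expect_lt(abs(sum(g$comps$area) / sec_area - 1), 1e-3)
  # triangle additivity along a root-to-tip path
  members <- g$branch_index[["8"]]
  tip <- members[which.max(g$comps$dist_soma[members])]
  mid <- g$comps$parent[tip]
  expect_equal(axial_path_resistance(g, g$soma, tip),
               axial_path_resistance(g, g$soma, mid) +
                 axial_path_resistance(g, mid, tip), tolerance = 1e-9)
})

test_that("distal branches report larger distance to soma within a limb", {
  g <- canonical_model()$graph
  cfg <- morphology_config()$branches
  # distance of the limb compartment each branch attaches to (independent
  # of the branch's own stem length)
  attach_dist <- vapply(as.character(1:22), function(b) {
    conn <- g$connection_segment[[b]]
    g$comps$dist_soma[g$comps$parent[conn]]
  }, numeric(1))
  for (l in 1:3) {
    ids <- cfg$branch_id[cfg$limb_id == l]
    d <- attach_dist[as.character(ids)][order(cfg$attach[match(ids, cfg$branch_id)])]
    expect_true(all(diff(d) >= 0))
    expect_gt(d[length(d)], d[1])
  }
})

test_that("SWC-like export round-trips", {
  g <- canonical_model()$graph
  f <- tempfile(fileext = ".swc")
  df <- write_swc_like(g, f)
  back <- read_swc_like(f)
  expect_equal(back$id, df$id)
  expect_equal(back$parent, df$parent)
  expect_equal(back$radius, df$radius, tolerance = 1e-8)
  unlink(f)
})
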