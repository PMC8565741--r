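test_that("graph construction canonicalizes undirected edges", {
  g <- pathway_graph(c("a", "b"), rbind(c("a", "b")))
  expect_equal(n_edges(g), 1L)
  expect_equal(count_components(g), 1L)

  # {u,v} and {v,u} collapse to one edge
  g2 <- pathway_graph(c("a", "b"), rbind(c("a", "b"), c("b", "a")))
  expect_equal(n_edges(g2), 1L)

  g3 <- pathway_graph(c("a", "b", "c"))
  expect_equal(n_edges(g3), 0L)
  expect_equal(count_components(g3), 3L)

  expect_error(pathway_graph(c("a", "b"), rbind(c("a", "x"))), "endpoint")
  expect_error(pathway_graph(c("a", "b"), rbind(c("a", "a"))), "loop")
  expect_error(pathway_graph(c("a", "a")), "duplicate")
})

test_that("normalized Laplacian matches hand-computed cases", {
  g2 <- pathway_graph(c("a", "b"), rbind(c("a", "b")))
  l2 <- normalized_laplacian(g2)
  expect_equal(unname(l2[, ]), rbind(c(1, -1), c(-1, 1)))
  expect_equal(eigen(l2, symmetric = TRUE)$values, c(2, 0))

  path3 <- pathway_graph(c("a", "b", "c"), rbind(c("a", "b"), c("b", "c")))
  l3 <- normalized_laplacian(path3)
  expect_equal(l3["a", "b"], -1 / sqrt(2))
  expect_equal(l3["b", "c"], -1 / sqrt(2))
  expect_equal(l3["a", "c"], 0)
  expect_equal(eigen(l3, symmetric = TRUE)$values, c(2, 1, 0))

  # isolated nodes get zero rows and columns, one zero eigenvalue each
  l0 <- normalized_laplacian(pathway_graph(c("a", "b", "c")))
  expect_equal(unname(l0[, ]), matrix(0, 3, 3))
})

test_that("regularized Laplacian is (I + tau L)^-1", {
  g2 <- pathway_graph(c("a", "b"), rbind(c("a", "b")))
  l2 <- normalized_laplacian(g2)

  expect_equal(unname(regularize_laplacian(l2, 0)[, ]), diag(2))
  # (I + L)^-1 = inverse of [[2,-1],[-1,2]] = (1/3)[[2,1],[1,2]]
  expect_equal(unname(regularize_laplacian(l2, 1)[, ]),
               rbind(c(2, 1), c(1, 2)) / 3)

  l0 <- normalized_laplacian(pathway_graph(letters[1:4]))
  expect_equal(unname(regularize_laplacian(l0, 7.3)[, ]), diag(4))

  expect_error(regularize_laplacian(diag(c(1, -1)), 1), "semidefinite")
  expect_error(regularize_laplacian(l2, -0.5), "nonnegative")
})

test_that("component count equals the zero-eigenvalue multiplicity", {
  path3 <- pathway_graph(c("a", "b", "c"), rbind(c("a", "b"), c("b", "c")))
  expect_equal(count_components(path3), 1L)
  expect_equal(count_components(pathway_graph(c("a", "b", "c"))), 3L)

  g <- pathway_graph(letters[1:4], rbind(c("a", "b"), c("c", "d")))
  expect_equal(count_components(g), 2L)
  ev <- eigen(normalized_laplacian(g), symmetric = TRUE)$values
  expect_equal(sum(abs(ev) < 1e-8 * max(1, max(ev))), 2L)
})

test_that("restriction to measured features induces the right subgraph", {
  path3 <- pathway_graph(c("a", "b", "c"), rbind(c("a", "b"), c("b", "c")))
  r1 <- restrict_to_measured(path3, c("a", "c"))
  expect_equal(r1$nodes, c("a", "c"))
  expect_equal(n_edges(r1), 0L)

  r2 <- restrict_to_measured(path3, c("a", "b", "c", "d"))
  expect_equal(r2, path3)

  tri <- pathway_graph(c("a", "b", "c"),
                       rbind(c("a", "b"), c("b", "c"), c("a", "c")))
  r3 <- restrict_to_measured(tri, c("b", "c"))
  expect_equal(n_edges(r3), 1L)

  expect_error(restrict_to_measured(path3, "z"),
               class = "netkat_empty_pathway")
})

test_that("Laplacian spectra satisfy their structural invariants", {
  set.seed(42)
  for (rep in 1:25) {
    g <- random_test_graph(sample(4:20, 1), runif(1, 0.05, 0.4))
    l <- normalized_laplacian(g)
    ev <- eigen(l, symmetric = TRUE, only.values = TRUE)$values
    expect_true(all(ev >= -1e-10) && all(ev <= 2 + 1e-10))
    expect_equal(sum(abs(ev) < 1e-8 * max(1, max(ev))),
                 count_components(g))

    tau <- runif(1, 0.1, 3)
    lr <- regularize_laplacian(l, tau)
    evr <- eigen(lr, symmetric = TRUE, only.values = TRUE)$values
    expect_equal(sort(evr), sort(1 / (1 + tau * ev)), tolerance = 1e-8)
    expect_true(min(evr) >= 1 / (1 + 2 * tau) - 1e-8 && max(evr) <= 1 + 1e-8)

    # relabeling permutes the matrices conformably
    perm <- sample(n_nodes(g))
    gp <- pathway_graph(g$nodes[perm],
                        if (nrow(g$edges)) {
                          cbind(g$nodes[g$edges[, 1]], g$nodes[g$edges[, 2]])
                        })
    lp <- normalized_laplacian(gp)
    expect_equal(unname(lp[, ]), unname(l[perm, perm]), tolerance = 1e-12)
    expect_equal(unname(regularize_laplacian(lp, tau)[, ]),
                 unname(lr[perm, perm]), tolerance = 1e-10)
  }
})
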