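# Hand-computed scalar examples for each path equation, plus the oracle
# equivalence and symmetry properties of the layer updates.

two_atom_graph <- function(type = "SINGLE", coords = NULL)
  molecular_graph(c("C", "C"), data.frame(i = 1, j = 2, type = type),
                  coords = coords)

test_that("node path reproduces the hand-evaluated pair/update example", {
  g <- two_atom_graph()
  par <- node_path_params(matrix(c(1, 1), 1), 0, matrix(1, 1, 1), 0)
  H <- matrix(c(1, 2), 2, 1)
  # P11=2, P12=3, P21=3, P22=4 -> H' = (relu(2+3), relu(3+4))
  expect_equal(node_path_update(H, g, par), matrix(c(5, 7), 2, 1),
               tolerance = 1e-9)

  iso <- molecular_graph("C")
  expect_equal(node_path_update(matrix(3, 1, 1), iso, par),
               matrix(6, 1, 1), tolerance = 1e-9)

  zero <- node_path_params(matrix(0, 1, 2), 0, matrix(0, 1, 1), 0)
  expect_equal(node_path_update(H, g, zero), matrix(0, 2, 1))
})

test_that("edge parameter matrix is the 1x1 convolution over bond channels", {
  g <- two_atom_graph()
  expect_equal(edge_parameter_matrix(g$A, 1:5, 0),
               matrix(c(1, 2, 2, 1), 2), tolerance = 1e-9)
  expect_equal(edge_parameter_matrix(g$A, rep(0, 5), 0), matrix(0, 2, 2))
  expect_equal(edge_parameter_matrix(g$A, c(1, 0, 0, 0, 0), 0), diag(2))
  # bias shifts every entry; symmetry preserved
  E <- edge_parameter_matrix(g$A, 1:5, 0.5)
  expect_equal(E, t(E))
  expect_equal(E[1, 2], 2.5)
})

test_that("edge path reproduces the fixed-mode example and reduces to the node path", {
  g <- two_atom_graph()
  H <- matrix(c(1, 2), 2, 1)
  par <- edge_path_params(matrix(c(1, 1), 1), 0, matrix(1, 1, 1), 0,
                          fixed_mode = TRUE)
  # E=[[1,2],[2,1]]: P11=2, P12=6, P21=6, P22=4 -> (8, 10)
  expect_equal(edge_path_update(H, g, par), matrix(c(8, 10), 2, 1),
               tolerance = 1e-9)

  # E == 1 everywhere on a SELF+SINGLE graph with shared weights == node path
  for (seed in 1:5) {
    gg <- rand_graph(seed + 40)
    gg$bonds$type <- "SINGLE"
    gg <- molecular_graph(gg$elements, gg$bonds, gg$C, num_h = gg$num_h,
                          charge = gg$charge)
    M <- 3
    np <- rand_node_par(M, seed)
    ep <- edge_path_params(np$W_np, np$B_np, np$W_n, np$B_n,
                           w = c(1, 1, 1, 1, 1), c = 0)
    H <- rand_H(gg$n_atoms, M, seed)
    expect_equal(edge_path_update(H, gg, ep), node_path_update(H, gg, np))
  }
})

test_that("relative coordinates are antisymmetric, zero-diagonal, translation-invariant", {
  C <- rbind(c(0, 0, 0), c(1, 0, 0))
  R <- relative_coords(C)
  expect_equal(R["x", , ], matrix(c(0, 1, -1, 0), 2), tolerance = 1e-12)
  expect_equal(R["y", , ], matrix(0, 2, 2))
  expect_equal(R["z", , ], matrix(0, 2, 2))
  set.seed(1)
  C <- matrix(rnorm(15), 5, 3)
  R <- relative_coords(C)
  for (k in 1:3) {
    expect_equal(R[k, , ], -t(R[k, , ]))
    expect_equal(diag(R[k, , ]), rep(0, 5))
  }
  expect_equal(relative_coords(C + 10), R)
})

test_that("3D path reproduces the hand examples with and without the self node", {
  g <- two_atom_graph(coords = rbind(c(0, 0, 0), c(1, 0, 0)))
  H <- matrix(c(1, 2), 2, 1)
  with_self <- threed_path_params(matrix(c(1, 1), 1), 0, matrix(1, 1, 1), 0,
                                  W_t = matrix(c(1, 1), 1),
                                  include_self = TRUE)
  # P12=relu(-3)=0, P21=3, Q=(0,3); H' = (relu(1+0), relu(2+3))
  expect_equal(threed_path_update(H, g, with_self), matrix(c(1, 5), 2, 1),
               tolerance = 1e-9)
  no_self <- threed_path_params(matrix(c(1, 1), 1), 0, matrix(1, 1, 1), 0,
                                include_self = FALSE, W_ns = matrix(1, 1, 1))
  expect_equal(threed_path_update(H, g, no_self), matrix(c(0, 3), 2, 1),
               tolerance = 1e-9)
})

test_that("3D path is translation invariant but changes under a witness rotation", {
  g <- rand_graph(7)
  M <- 3
  par <- rand_threed_par(M, 7)
  H <- rand_H(g$n_atoms, M, 7)
  out <- threed_path_update(H, g, par)
  shift <- matrix(rep(c(3, -1, 10), each = g$n_atoms), ncol = 3)
  g_shift <- molecular_graph(g$elements, g$bonds, g$C + shift,
                             num_h = g$num_h, charge = g$charge)
  expect_equal(threed_path_update(H, g_shift, par), out, tolerance = 1e-12)

  theta <- pi / 3
  Rot <- rbind(c(cos(theta), -sin(theta), 0),
               c(sin(theta), cos(theta), 0),
               c(0, 0, 1))
  g_rot <- molecular_graph(g$elements, g$bonds, g$C %*% t(Rot),
                           num_h = g$num_h, charge = g$charge)
  expect_gt(max(abs(threed_path_update(H, g_rot, par) - out)), 1e-6)
})

test_that("vectorized path updates agree with the per-node loop oracle", {
  for (seed in 1:100) {
    M <- sample(1:8, 1)
    g <- rand_graph(seed, n_max = 8L)
    H <- rand_H(g$n_atoms, M, seed)
    np <- rand_node_par(M, seed)
    expect_equal(node_path_update(H, g, np), oracle_node_update(H, g, np),
                 tolerance = 1e-6)
    ep <- rand_edge_par(M, seed + 1000)
    expect_equal(edge_path_update(H, g, ep), oracle_edge_update(H, g, ep),
                 tolerance = 1e-6)
    tp <- rand_threed_par(M, seed + 2000,
                          include_self = seed %% 2 == 0)
    expect_equal(threed_path_update(H, g, tp), oracle_threed_update(H, g, tp),
                 tolerance = 1e-6)
    expect_equal(edge_parameter_matrix(g$A, ep$w, ep$c),
                 oracle_E(g$A, ep$w, ep$c), tolerance = 1e-9)
  }
})

test_that("path updates are nonnegative and permutation equivariant", {
  for (seed in 1:10) {
    M <- 4
    g <- rand_graph(seed, n_max = 8L)
    H <- rand_H(g$n_atoms, M, seed)
    np <- rand_node_par(M, seed)
    ep <- rand_edge_par(M, seed)
    tp <- rand_threed_par(M, seed)
    outs <- list(node = node_path_update(H, g, np),
                 edge = edge_path_update(H, g, ep),
                 td = threed_path_update(H, g, tp))
    for (o in outs) expect_true(all(o >= 0))

    set.seed(seed + 500)
    perm <- sample(g$n_atoms)
    gp <- permute_graph(g, perm)
    Hp <- H[perm, , drop = FALSE]
    expect_equal(node_path_update(Hp, gp, np), outs$node[perm, , drop = FALSE],
                 tolerance = 1e-10)
    expect_equal(edge_path_update(Hp, gp, ep), outs$edge[perm, , drop = FALSE],
                 tolerance = 1e-10)
    expect_equal(threed_path_update(Hp, gp, tp), outs$td[perm, , drop = FALSE],
                 tolerance = 1e-10)
  }
})

test_that("shape mismatches raise informative errors", {
  g <- two_atom_graph()
  par <- rand_node_par(3, 1)
  expect_error(node_path_update(matrix(1, 2, 2), g, par), "expected")
  expect_error(node_path_update(matrix(1, 3, 3), g, par), "expected")
  g_nc <- molecular_graph(c("C", "C"), data.frame(i = 1, j = 2,
                                                  type = "SINGLE"))
  expect_error(threed_path_update(matrix(1, 2, 3), g_nc, rand_threed_par(3, 2)),
               "coordinates")
  expect_error(relative_coords(NULL), "coordinates")
})
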