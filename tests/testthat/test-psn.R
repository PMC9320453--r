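# hand-constructed structures: residue-center beads with chosen identities
bead_structure <- function(resids, coords) {
  atoms <- ca_atoms(length(resids))
  atoms$resid <- resids
  structure(list(atoms = atoms, coords = coords, model_id = 1L),
            class = "mdh_structure")
}

# minimal all-atom Asp + Lys pair with the charged groups `gap` apart
asp_lys_frame <- function(gap) {
  atoms <- data.frame(
    serial = 1:6,
    elety = c("CA", "CB", "OD1", "CA", "CE", "NZ"),
    resno = c(1L, 1L, 1L, 3L, 3L, 3L),
    resid = c("ASP", "ASP", "ASP", "LYS", "LYS", "LYS"),
    chain = "A", element = c("C", "C", "O", "C", "C", "N"),
    mass = 12, stringsAsFactors = FALSE
  )
  coords <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0),
                  c(2 + gap + 3, 0, 0), c(2 + gap + 1.5, 0, 0), c(2 + gap, 0, 0))
  structure(list(atoms = atoms, coords = coords, model_id = 1L),
            class = "mdh_structure")
}

test_that("salt-bridge detection respects the charged-group cutoff", {
  pp <- psn_params("all_atom")
  hit <- detect_interactions(asp_lys_frame(4.0), "SB", pp)
  expect_equal(nrow(hit), 1L)
  expect_equal(c(hit$residue_a, hit$residue_b), c(1L, 3L))
  expect_equal(nrow(detect_interactions(asp_lys_frame(5.0), "SB", pp)), 0L)
  expect_error(detect_interactions(asp_lys_frame(4), "XX", pp),
               class = "mdh_config_error")
})

test_that("hydrophobic contacts require the hydrophobic identity and the cutoff", {
  pp <- psn_params("residue_center")
  place <- function(resids, d) {
    bead_structure(resids, rbind(c(0, 0, 0), c(100, 0, 0), c(d, 0, 0)))
  }
  # Leu-Leu at 4.9 A -> detected; Ser-Leu at the same distance -> not
  hit <- detect_interactions(place(c("LEU", "GLY", "LEU"), 4.9), "HC", pp)
  expect_equal(nrow(hit), 1L)
  expect_equal(nrow(detect_interactions(place(c("SER", "GLY", "LEU"), 4.9),
                                        "HC", pp)), 0L)
  # never at 5.1 A; never a residue with itself; adjacent residues excluded
  expect_equal(nrow(detect_interactions(place(c("LEU", "GLY", "LEU"), 5.1),
                                        "HC", pp)), 0L)
  adj <- bead_structure(c("LEU", "LEU"), rbind(c(0, 0, 0), c(3, 0, 0)))
  expect_equal(nrow(detect_interactions(adj, "HC", pp)), 0L)
  # all-atom mode refuses a C-alpha-only model
  expect_error(detect_interactions(adj, "HC", psn_params("all_atom")),
               class = "mdh_config_error")
})

test_that("detection is symmetric and deterministic", {
  set.seed(61)
  resids <- sample(c("LEU", "SER", "ASP", "LYS", "VAL"), 12, replace = TRUE)
  x <- matrix(rnorm(36, sd = 4), 12, 3)
  s <- bead_structure(resids, x)
  pp <- psn_params("residue_center")
  h1 <- detect_interactions(s, "HC", pp)
  h2 <- detect_interactions(s, "HC", pp)
  expect_identical(h1, h2)
  expect_true(all(h1$residue_a < h1$residue_b))
  # reversing atom order in the frame does not change the detected pairs
  s_rev <- bead_structure(rev(resids), x[12:1, , drop = FALSE])
  s_rev$atoms$resno <- 12:1
  h3 <- detect_interactions(s_rev, "HC", pp)
  o <- order(h3$residue_a, h3$residue_b)
  expect_equal(h3[o, ], h1[order(h1$residue_a, h1$residue_b), ],
               ignore_attr = TRUE)
})

test_that("persistence is the exact fraction of production frames", {
  # residues 1 and 3 (LEU) in contact in exactly 70 of 100 frames
  near <- rbind(c(0, 0, 0), c(50, 0, 0), c(4, 0, 0))
  far <- rbind(c(0, 0, 0), c(50, 0, 0), c(20, 0, 0))
  frames <- c(rep(list(near), 70), rep(list(far), 30))
  atoms <- ca_atoms(3, resid = "LEU")
  traj <- traj_from_coords(frames, atoms)
  rec <- interaction_persistence(traj, "HC", psn_params("residue_center"))
  expect_equal(nrow(rec), 1L)
  expect_identical(rec$persistence, 0.70)

  # a pair never within the cutoff is absent
  traj_far <- traj_from_coords(rep(list(far), 10), atoms)
  expect_equal(nrow(interaction_persistence(traj_far, "HC",
                                            psn_params("residue_center"))), 0L)

  # production window restriction: contact holds in all production frames
  rec2 <- interaction_persistence(traj, "HC", psn_params("residue_center"),
                                  production_start = 1L)
  rec3 <- interaction_persistence(
    traj_from_coords(frames[1:70], atoms), "HC", psn_params("residue_center"))
  expect_equal(rec3$persistence, 1.0)
  expect_error(interaction_persistence(traj, "HC", psn_params(),
                                       production_start = 200L),
               class = "mdh_param_error")
  expect_equal(rec2$persistence, 0.70)
})

test_that("p_crit follows the largest-cluster-drop criterion with its tie-break", {
  ladder <- data.frame(
    residue_a = c(1L, 3L, 5L, 7L, 9L, 2L, 4L, 6L, 8L),
    residue_b = c(2L, 4L, 6L, 8L, 10L, 3L, 5L, 7L, 9L),
    class = "HC",
    persistence = c(rep(0.9, 5), rep(0.35, 4))
  )
  # hand enumeration: p <= 0.35 -> one 10-residue chain (size 10);
  # 0.36 <= p <= 0.90 -> five isolated pairs (size 2); p > 0.90 -> size 1.
  pc <- persistence_threshold(ladder, step = 0.02)
  sizes <- attr(pc, "cluster_sizes")
  ps <- attr(pc, "thresholds")
  expect_equal(sizes[ps <= 0.35], rep(10L, sum(ps <= 0.35)))
  expect_equal(sizes[ps >= 0.36 & ps <= 0.90], rep(2L, sum(ps >= 0.36 & ps <= 0.90)))
  expect_equal(sizes[ps >= 0.92], rep(1L, sum(ps >= 0.92)))
  expect_true(all(diff(sizes) <= 0))  # non-increasing in the threshold
  expect_equal(as.numeric(pc), 0.36)  # drop 10 -> 2 beats drop 2 -> 1

  # single record at 0.5: the only drop (2 -> 1) is at the 0.52 boundary
  single <- data.frame(residue_a = 1L, residue_b = 3L, class = "HC",
                       persistence = 0.5)
  expect_equal(as.numeric(persistence_threshold(single, step = 0.02)), 0.52)

  # all persistences 1.0: size never drops inside the scan; final boundary
  flat <- data.frame(residue_a = c(1L, 3L), residue_b = c(3L, 5L),
                     class = "HC", persistence = 1.0)
  expect_equal(as.numeric(persistence_threshold(flat, step = 0.02)), 1.0)

  expect_error(persistence_threshold(flat[0, ]), class = "mdh_config_error")
})

test_that("merged PSN degrees match hand counts", {
  pc <- c(SB = 0.5, HB = 0.5, HC = 0.5)
  # empty input
  empty <- data.frame(residue_a = integer(0), residue_b = integer(0),
                      class = character(0), persistence = numeric(0))
  g0 <- build_psn(empty, pc, nodes = 1:4)
  expect_equal(unname(g0$degree), rep(0L, 4))

  # triangle
  tri <- data.frame(residue_a = c(1L, 3L, 1L), residue_b = c(3L, 5L, 5L),
                    class = "SB", persistence = 0.9)
  gt <- build_psn(tri, pc)
  expect_equal(unname(gt$degree), c(2L, 2L, 2L))

  # 8-residue system, hand-enumerated
  recs <- data.frame(
    residue_a = c(1L, 1L, 1L, 3L, 2L, 5L, 4L),
    residue_b = c(3L, 3L, 5L, 5L, 7L, 8L, 6L),
    class = c("SB", "HB", "HB", "HC", "HB", "SB", "HC"),
    persistence = c(0.9, 0.95, 0.8, 0.7, 0.6, 0.9, 0.2)
  )
  g <- build_psn(recs, pc, nodes = 1:8)
  expect_equal(g$degree[as.character(1:8)],
               c(`1` = 2L, `2` = 1L, `3` = 2L, `4` = 0L, `5` = 3L, `6` = 0L,
                 `7` = 1L, `8` = 1L))
  expect_equal(sum(g$degree), 2L * igraph::ecount(g$graph))
  # per-class counting: the doubly-linked 1-3 pair now counts twice
  g2 <- build_psn(recs, pc, nodes = 1:8, per_class_degree = TRUE)
  expect_equal(unname(g2$degree[c("1", "3")]), c(3L, 3L))

  # raising a threshold never adds edges
  g_hi <- build_psn(recs, c(SB = 0.95, HB = 0.9, HC = 0.9), nodes = 1:8)
  expect_lte(nrow(g_hi$edges), nrow(g$edges))
  expect_true(all(g_hi$degree <= g$degree))
})

test_that("hub rule is strict and spans systems", {
  pc <- c(SB = 0.5, HB = 0.5, HC = 0.5)
  g7 <- build_psn(star_records(100L, c(1:5, 8L, 10L)), pc)  # degree 7
  g6 <- build_psn(star_records(100L, c(1:5, 8L)), pc)       # degree 6
  hubs <- find_hubs(list(A = g7), k_min = 6L)
  expect_true(100L %in% hubs$residue)
  expect_false(any(find_hubs(list(A = g6), k_min = 6L)$residue == 100L))

  # hub in one system only, degrees reported for all systems
  g5 <- build_psn(star_records(100L, c(1:4, 8L)), pc)       # degree 5
  g1 <- build_psn(star_records(100L, 1L), pc)
  hb <- find_hubs(list(A = g5, B = g1), k_min = 4L)
  expect_true(100L %in% hb$residue)
  row <- hb[hb$residue == 100L, ]
  expect_equal(row$degree.A, 5L)
  expect_equal(row$degree.B, 1L)

  # monotone: hubs at k>6 are a subset of hubs at k>4
  hset <- function(k) find_hubs(list(A = g7, B = g5), k_min = k)$residue
  expect_true(all(hset(6L) %in% hset(4L)))
  expect_error(find_hubs(list(), 4L), class = "mdh_config_error")
})

test_that("delta-degree arithmetic and the edge-sum identity", {
  pc <- c(SB = 0.5, HB = 0.5, HC = 0.5)
  g <- build_psn(star_records(1L, c(3L, 5L, 7L)), pc, nodes = 1:8)
  dd <- delta_degree(g, g)
  expect_true(all(dd$delta_degree == 0L))

  g_open <- build_psn(star_records(1L, c(3L, 5L, 7L)), pc, nodes = 1:8)   # k(1)=3
  g_closed <- build_psn(star_records(1L, c(3L, 5L, 7L, 4L, 6L)), pc, nodes = 1:8)
  dd <- delta_degree(g_open, g_closed)
  expect_equal(dd$delta_degree[dd$residue == 1L], -2L)
  # sum of delta-degrees = 2 * (E_open - E_closed)
  expect_equal(sum(dd$delta_degree),
               2L * (igraph::ecount(g_open$graph) - igraph::ecount(g_closed$graph)))
  # an open graph that loses edges is negative for most residues
  expect_gte(sum(dd$delta_degree <= 0L), 6L)
})

test_that("inter-domain tables keep only persistent cross-domain records", {
  dset <- domain_set(list(I = list(c(1, 10)), III = list(c(21, 30))))
  pc <- c(SB = 0.5, HB = 0.5, HC = 0.5)
  recs <- data.frame(
    residue_a = c(2L, 25L, 3L, 5L),
    residue_b = c(24L, 4L, 7L, 28L),     # 25-4 arrives domain-III-first
    class = c("SB", "HB", "HC", "SB"),
    persistence = c(0.8, 0.9, 0.95, 0.4) # last one below threshold
  )
  tab <- interdomain_table(recs, pc, dset, "I", "III")
  expect_equal(nrow(tab), 2L)                # 3-7 is intra-domain, 5-28 weak
  expect_true(all(tab$residue_a %in% 1:10))
  expect_true(all(tab$residue_b %in% 21:30))
  expect_equal(tab$persistence, sort(tab$persistence, decreasing = TRUE))

  expect_equal(nrow(interdomain_table(recs[0, ], pc, dset, "I", "III")), 0L)
  # overlapping domains are rejected at construction already
  expect_error(domain_set(list(I = list(c(1, 10)), III = list(c(5, 30)))),
               class = "mdh_config_error")
})
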