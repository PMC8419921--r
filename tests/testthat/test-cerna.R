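# Seed-match target prediction, co-expression gating, network assembly and
# round-trip export.

test_that("seed-site classes follow their definitions on constructed targets", {
  mir <- "UGAGGUAGUAGGUUGUAUAGUU" # 22 nt, seed GAGGUA
  core <- "TACCTC"                # reverse complement of positions 2-7
  pad <- strrep("G", 10)
  t8 <- paste0(pad, "C", core, "A", pad)  # m8 pairing + A1
  t7m8 <- paste0(pad, "C", core, "G", pad)
  t7a1 <- paste0(pad, "T", core, "A", pad)
  t6 <- paste0(pad, "T", core, "G", pad)
  targets <- c(t8 = t8, t7m8 = t7m8, t7a1 = t7a1, t6 = t6)
  out <- predict_targets(c(mir = mir), targets, "mRNA")
  expect_equal(nrow(out), 4)
  got <- setNames(out$site_type, out$target_id)
  expect_equal(got[["t8"]], "8mer")
  expect_equal(got[["t7m8"]], "7mer-m8")
  expect_equal(got[["t7a1"]], "7mer-A1")
  expect_equal(got[["t6"]], "6mer")
  expect_true(all(out$position == 12))
  # no complement of the seed anywhere -> zero edges
  none <- predict_targets(c(mir = mir), c(x = strrep("G", 50)), "mRNA")
  expect_equal(nrow(none), 0)
  expect_error(predict_targets(c(m = "ACGTNACG"), c(x = strrep("A", 20))),
               "non-ACGT")
  expect_error(predict_targets(c(m = "ACGT"), c(x = strrep("A", 20))),
               ">= 8 nt")
})

test_that("predicted edges equal the sliding-window oracle on random sequences", {
  withr::with_seed(77, {
    mirs <- setNames(vapply(1:10, function(i)
      paste(sample(c("A", "C", "G", "U"), 21, TRUE), collapse = ""), ""),
      paste0("mir", 1:10))
    tgts <- setNames(vapply(1:5, function(i)
      paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = ""), ""),
      paste0("t", 1:5))
  })
  got <- predict_targets(mirs, tgts, "mRNA")
  for (m in names(mirs)) for (tg in names(tgts)) {
    want <- oracle_seed_sites(chartr("U", "T", mirs[m]), tgts[tg])
    sub <- got[got$mirna_id == m & got$target_id == tg, ]
    expect_equal(sub$position, want$position)
    expect_equal(sub$site_type, want$site_type)
  }
})

test_that("correlation edges match closed-form statistics and textbook BH", {
  withr::with_seed(21, {
    mat <- matrix(rnorm(40 * 18), 40, dimnames = list(paste0("g", 1:40)))
    pairs <- data.frame(x_id = paste0("g", sample(1:40, 100, TRUE)),
                        y_id = paste0("g", sample(1:40, 100, TRUE)),
                        stringsAsFactors = FALSE)
    pairs <- pairs[pairs$x_id != pairs$y_id, ]
  })
  ce <- correlate_pairs(mat, mat, pairs)
  for (i in seq_len(nrow(ce))) {
    ct <- cor.test(mat[ce$x_id[i], ], mat[ce$y_id[i], ])
    expect_equal(ce$pearson_r[i], unname(ct$estimate), tolerance = 1e-12)
    expect_equal(ce$p_value[i], ct$p.value, tolerance = 1e-12)
  }
  expect_equal(ce$adj_p, oracle_bh(ce$p_value), tolerance = 1e-12)
  expect_true(all(ce$pearson_r >= -1 & ce$pearson_r <= 1))
})

test_that("identity, perfect linearity, and zero variance are handled", {
  m <- rbind(a = c(1, 2, 3, 4, 5), b = c(2, 4, 6, 8, 10),
             c = c(5, 5, 5, 5, 5), d = c(2, 1, 7, 3, 9))
  ce <- correlate_pairs(m, m, data.frame(x_id = c("a", "a", "c"),
                                         y_id = c("a", "b", "d")))
  expect_equal(ce$pearson_r[1], 1)
  expect_equal(ce$pearson_r[2], 1) # y = 2x
  expect_true(ce$retained[2])
  expect_true(is.na(ce$pearson_r[3])) # zero variance: skipped, logged
  expect_equal(attr(ce, "skipped")$reason, "zero_variance")
  expect_error(correlate_pairs(m[, 1:2], m[, 1:2],
                               data.frame(x_id = "a", y_id = "b")),
               ">= 3")
})

test_that("assembled triplets satisfy the four-part invariant", {
  de <- data.frame(
    feature_id = c("circ1", "mir1", "gene1", "gene2", "lnc1", "mir2"),
    class = c("circRNA", "miRNA", "mRNA", "mRNA", "lncRNA", "miRNA"),
    status = c("up", "down", "up", "ns", "up", "up"),
    stringsAsFactors = FALSE)
  edges <- data.frame(
    mirna_id = c("mir1", "mir1", "mir1", "mir2", "mir2"),
    target_id = c("circ1", "gene1", "gene2", "lnc1", "gene1"),
    target_class = c("circRNA", "mRNA", "mRNA", "lncRNA", "mRNA"),
    site_type = "8mer", position = 1L, stringsAsFactors = FALSE)
  co <- data.frame(x_id = c("circ1", "circ1", "lnc1"),
                   y_id = c("gene1", "gene2", "gene1"),
                   pearson_r = c(0.99, 0.99, 0.95),
                   p_value = 1e-8, adj_p = 1e-6,
                   retained = c(TRUE, TRUE, TRUE), stringsAsFactors = FALSE)
  net <- assemble_network(de, edges, co)
  # (circ1, mir1, gene1): all DE, same direction ceRNA/mRNA, miRNA opposite
  expect_equal(nrow(net$triplets), 1)
  expect_equal(net$triplets$cerna_id, "circ1")
  expect_equal(net$triplets$subnetwork, "circ-up")
  # gene2 is ns -> excluded despite target + coexpression support;
  # (lnc1, mir2, gene1): miRNA shares the ceRNA direction -> excluded by
  # the miRNA-direction rule but logged
  excl <- attr(net, "mirna_direction_excluded")
  expect_equal(nrow(excl), 1)
  expect_equal(excl$cerna_id, "lnc1")
  # ... and admitted under the permissive rule
  net2 <- assemble_network(de, edges, co, mirna_rule = "any")
  expect_equal(nrow(net2$triplets), 2)
  # unknown feature in edges is a hard error listing the id
  bad <- rbind(edges, data.frame(mirna_id = "mir9", target_id = "gene1",
                                 target_class = "mRNA", site_type = "6mer",
                                 position = 2L))
  expect_error(assemble_network(de, bad, co), "mir9")
})

test_that("raising r_cut or lowering adjp_cut never adds triplets", {
  tp <- tiny_planted(seed = 91)
  es <- simulate_expression(tp$truth, seed = 92)
  f <- tp$truth$features
  counts <- do.call(rbind, lapply(es$matrices, `[[`, "counts"))
  lmat <- log2(counts + 1)
  tab <- emit_target_tables(tp$genome, tp$truth)
  pairs <- candidate_pairs(tab)
  pairs <- pairs[pairs$x_id %in% rownames(lmat) &
                 pairs$y_id %in% rownames(lmat), ]
  de <- do.call(rbind, lapply(split(f$feature_id, f$class), function(ids) {
    de_screen(counts[ids, , drop = FALSE], es$groups, paired = TRUE,
              rna_class = f$class[match(ids[1], f$feature_id)])
  }))
  tab <- tab[tab$target_id %in% de$feature_id, ]
  n_trip <- function(r_cut, adjp_cut) {
    co <- correlate_pairs(lmat, lmat, pairs, r_cut = r_cut,
                          adjp_cut = adjp_cut)
    nrow(assemble_network(de, tab, co)$triplets)
  }
  base <- n_trip(0.9, 0.1)
  expect_gt(base, 0)
  expect_lte(n_trip(0.95, 0.1), base)
  expect_lte(n_trip(0.9, 0.001), base)
  expect_gte(n_trip(0.5, 0.2), base)
})

test_that("networks round-trip through SIF and GraphML", {
  de <- data.frame(feature_id = c("c1", "m1", "g1"),
                   class = c("circRNA", "miRNA", "mRNA"),
                   status = c("up", "down", "up"), stringsAsFactors = FALSE)
  edges <- data.frame(mirna_id = "m1", target_id = c("c1", "g1"),
                      target_class = c("circRNA", "mRNA"),
                      site_type = "8mer", position = 1L,
                      stringsAsFactors = FALSE)
  co <- data.frame(x_id = "c1", y_id = "g1", pearson_r = 0.99,
                   p_value = 1e-9, adj_p = 1e-7, retained = TRUE,
                   stringsAsFactors = FALSE)
  net <- assemble_network(de, edges, co)
  expect_equal(nrow(net$nodes), 3)
  expect_equal(nrow(net$edges), 3)

  sif <- tempfile(fileext = ".sif")
  export_network(net, sif)
  imp <- import_network(sif)
  expect_setequal(imp$nodes$id, net$nodes$id)
  expect_equal(nrow(imp$edges), 3)
  sif2 <- tempfile(fileext = ".sif")
  export_network(structure(list(nodes = imp$nodes, edges = imp$edges),
                           class = "cerna_network"), sif2)
  expect_identical(readLines(sif), readLines(sif2)) # byte-identical

  gml <- tempfile(fileext = ".graphml")
  export_network(net, gml)
  impg <- import_network(gml)
  expect_setequal(impg$nodes$id, net$nodes$id)
  expect_setequal(paste(impg$nodes$class, impg$nodes$status),
                  paste(net$nodes$class, net$nodes$status))
  expect_setequal(impg$edges$type, net$edges$type)
  gml2 <- tempfile(fileext = ".graphml")
  export_network(structure(list(nodes = impg$nodes, edges = impg$edges),
                           class = "cerna_network"), gml2)
  expect_identical(readLines(gml), readLines(gml2))
})
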