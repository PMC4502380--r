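sim_anchor <- function() cached("anchor", {
  cfg <- sim_config(n_f2 = 250, n_chromosomes = 3,
                    scaffold_lengths = stats::setNames(rep(2e6, 15), paste0("S", 1:15)),
                    snp_density = 120, mean_coverage = 1.5, error_rate = 0.01,
                    seed = 71)
  sim <- simulate_cross(cfg)
  sv <- sieve_snps(sim$counts)
  geno <- bin_genotypes(binGBS:::subset_snps(sim$counts, which(sv$keep)),
                        cfg$scaffold_lengths)
  map <- build_linkage_map(apply_qc(geno)$geno)
  list(sim = sim, geno = geno, map = map)
})

test_that("scaffold orientation follows the bp-cM rank correlation", {
  expect_equal(orient_scaffold(c(1e5, 5e5, 9e5), c(0, 2, 4)), "+")
  expect_equal(orient_scaffold(c(1e5, 5e5, 9e5), c(4, 2, 0)), "-")
  expect_equal(orient_scaffold(5e5, 2), "unknown")          # single marker
  expect_equal(orient_scaffold(c(1e5, 9e5), c(2, 2)), "unknown")  # tied cM
})

test_that("anchoring against an unscrambled prior reports no changes or conflicts", {
  fx <- sim_anchor()
  anc <- anchor_scaffolds(fx$map, fx$sim$truth$placement)
  expect_equal(nrow(anc$changes), 0)
  expect_null(anc$conflicts)
  # every scaffold keeps its true chromosome and rank order
  tr <- fx$sim$truth$placement
  m <- match(anc$placements$scaffold, tr$scaffold)
  expect_equal(anc$placements$chromosome, tr$chromosome[m])
  expect_equal(anc$placements$rank, tr$rank[m])
  # anchored fraction never drops below the prior's
  expect_gte(nrow(anc$placements), sum(!is.na(tr$chromosome)))
})

test_that("scrambled assemblies are repaired: unanchored, flipped and moved scaffolds", {
  fx <- sim_anchor()
  scr <- scramble_assembly(fx$sim$truth, n_unanchor = 3, n_flip = 3, n_move = 1,
                           seed = 72)
  anc <- anchor_scaffolds(fx$map, scr$placement)
  tr <- fx$sim$truth$placement
  # unanchored scaffolds recover their true chromosome
  un <- scr$log$scaffold[scr$log$edit == "unanchored"]
  m <- match(un, anc$placements$scaffold)
  expect_true(all(!is.na(m)))
  expect_equal(anc$placements$chromosome[m],
               tr$chromosome[match(un, tr$scaffold)])
  expect_true(all(anc$changes$change[match(un, anc$changes$scaffold)] ==
                    "newly_anchored"))
  # flipped scaffolds are reported reoriented and their map orientation is
  # the reverse of the scrambled prior
  fl <- scr$log$scaffold[scr$log$edit == "flipped"]
  expect_true(all(fl %in% anc$changes$scaffold[anc$changes$change == "reoriented"]))
  # moved scaffold flagged as rearranged
  mv <- scr$log$scaffold[scr$log$edit == "moved"]
  expect_true(all(mv %in% anc$changes$scaffold[anc$changes$change == "rearranged"]))
})

test_that("scaffolds with markers on two chromosomes become conflicts, not placements", {
  fx <- sim_anchor()
  map <- fx$map
  # engineer a split: relabel one scaffold's marker as belonging to another
  victim <- map$scaffold[1]
  donor_row <- which(map$group != map$group[1])[1]
  map$scaffold[donor_row] <- victim
  anc <- anchor_scaffolds(map, fx$sim$truth$placement)
  expect_false(victim %in% anc$placements$scaffold)
  expect_true(victim %in% anc$conflicts$scaffold)
})

test_that("consensus accepts agreements and single-cross placements, reports conflicts", {
  pA <- data.frame(scaffold = c("S1", "S2", "S3"), chromosome = c("chr1", "chr1", "chr2"),
                   rank = c(1, 2, 1), orientation = c("+", "-", "+"),
                   evidence = "map", n_markers = c(3, 3, 3),
                   cM_span = 1, cM_mid = c(0, 5, 2), stringsAsFactors = FALSE)
  pB <- data.frame(scaffold = c("S1", "S2", "S4"), chromosome = c("chr1", "chr2", "chr2"),
                   rank = c(1, 1, 2), orientation = c("+", "unknown", "-"),
                   evidence = "map", n_markers = c(2, 2, 2),
                   cM_span = 1, cM_mid = c(1, 4, 9), stringsAsFactors = FALSE)
  cons <- consensus_map(pA, pB)
  p <- cons$placements
  expect_equal(p$evidence[p$scaffold == "S1"], "consensus")
  expect_equal(p$evidence[p$scaffold == "S3"], "map_crossA")
  expect_equal(p$evidence[p$scaffold == "S4"], "map_crossB")
  expect_false("S2" %in% p$scaffold)          # chr1 vs chr2: conflict
  expect_equal(cons$conflicts$scaffold, "S2")
  # identical inputs give an identical consensus
  cons2 <- consensus_map(pA, pA)
  expect_equal(cons2$placements$scaffold[order(cons2$placements$rank)][1:2],
               pA$scaffold[order(pA$rank)][1:2])
  expect_null(cons2$conflicts)
})

test_that("read-count correlation places unanchored bins near their true location", {
  fx <- sim_anchor()
  geno <- fx$geno; map <- fx$map
  # pretend one scaffold was never mapped; place its bins by correlation
  hidden <- "S8"
  hid_rows <- which(geno$markers$scaffold == hidden)
  placed <- map[map$scaffold != hidden, ]
  dos <- genotype_dosage(geno)
  placed_dos <- dos[match(placed$marker, rownames(dos)), , drop = FALSE]
  hid_dos <- dos[hid_rows, , drop = FALSE]
  res <- correlate_unplaced(hid_dos, placed_dos,
                            data.frame(marker = placed$marker,
                                       chromosome = placed$group,
                                       cM = placed$cM))
  expect_true(all(res$placed))
  truth_chr <- fx$sim$truth$placement$chromosome[
    fx$sim$truth$placement$scaffold == hidden]
  # the assigned group must be the group holding that chromosome's markers
  grp_of_chr <- unique(placed$group[
    fx$sim$truth$placement$chromosome[
      match(placed$scaffold, fx$sim$truth$placement$scaffold)] == truth_chr])
  expect_true(all(res$chromosome == grp_of_chr))
  # assigned within ~5 cM of the scaffold's true neighbourhood
  neigh <- range(map$cM[map$scaffold %in%
    fx$sim$truth$placement$scaffold[fx$sim$truth$placement$chromosome == truth_chr]])
  expect_true(all(res$cM >= neigh[1] - 5 & res$cM <= neigh[2] + 5))
  # all-missing dosages stay unplaced
  res2 <- correlate_unplaced(matrix(NA_real_, 1, ncol(dos)), placed_dos,
                             data.frame(marker = placed$marker,
                                        chromosome = placed$group,
                                        cM = placed$cM))
  expect_false(res2$placed)
})

test_that("liftover is strand-aware, length-preserving and bijective", {
  pl <- data.frame(scaffold = c("A", "B", "C"),
                   chromosome = c("chr1", "chr1", NA),
                   rank = c(1, 2, NA), orientation = c("+", "-", "unknown"),
                   stringsAsFactors = FALSE)
  lens <- c(A = 1000, B = 500, C = 300)
  lt <- build_liftover(pl, lens, gap_bp = 100)
  expect_equal(lt$c_start, c(1, 1101))
  expect_equal(lt$c_end - lt$c_start + 1, c(1000, 500))
  # forward positions
  expect_equal(liftover("A", 1, lt)$pos, 1)
  expect_equal(liftover("A", 1000, lt)$pos, 1000)
  expect_equal(liftover("B", 1, lt)$pos, 1600)     # reflected
  expect_equal(liftover("B", 500, lt)$pos, 1101)
  expect_false(liftover("C", 10, lt)$mapped)       # unplaced
  # gap position has no inverse
  expect_false(liftover_inverse("chr1", 1050, lt)$mapped)
  # round trip on random positions
  set.seed(73)
  scf <- sample(c("A", "B"), 1000, TRUE)
  pos <- ifelse(scf == "A", sample.int(1000, 1000, TRUE), sample.int(500, 1000, TRUE))
  fwd <- liftover(scf, pos, lt)
  expect_true(all(fwd$mapped))
  back <- liftover_inverse(fwd$chromosome, fwd$pos, lt)
  expect_equal(back$scaffold, scf)
  expect_equal(back$pos, pos)
})
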