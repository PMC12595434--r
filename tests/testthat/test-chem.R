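## lead compounds, built from their IUPAC names
MBE1_SMILES <- "CCc1cnccc1C(=O)Nc1cc2CCC(=O)Nc2cc1F"
MBE15_SMILES <- "CCc1ccccc1C(=O)Nc1cc2CCC(=O)Nc2cc1F"

test_that("SMILES parsing skips invalid records with a reason", {
  path <- withr::local_tempfile(fileext = ".smi")
  writeLines(c(paste(MBE1_SMILES, "mbe1"),
               "c1ccccc1 benzene",
               "CC(=O)O aceticacid",
               "notasmiles((("), path)
  cs <- parse_structures(path)
  expect_equal(nrow(cs$table), 3L)
  expect_equal(cs$skipped$record, 4L)
  expect_match(cs$skipped$reason, "unparseable")
  expect_error(parse_structures(withr::local_tempfile(fileext = ".smi")),
               "not found")
  p2 <- withr::local_tempfile(fileext = ".smi")
  writeLines("junk(((", p2)
  expect_error(parse_structures(p2), "no valid SMILES")
})

test_that("descriptors match the lead-compound reference values", {
  cs <- compute_descriptors(compound_set_from_smiles(
    c(MBE1_SMILES, MBE15_SMILES), c("MBE1", "MBE1.5")))
  tab <- cs$table
  expect_equal(round(tab$mw), c(313, 312))
  expect_equal(round(tab$tpsa), c(71, 58))
  expect_equal(tab$hbd, c(2, 2))
  expect_equal(tab$hba, c(5, 4))
})

test_that("benzene has no polar surface or hydrogen bonding capacity", {
  cs <- compute_descriptors(compound_set_from_smiles("c1ccccc1"))
  expect_equal(cs$table$tpsa, 0)
  expect_equal(cs$table$hbd, 0)
  expect_equal(cs$table$hba, 0)
  expect_equal(cs$table$mw, 78.11, tolerance = 0.01)
})

test_that("descriptors are invariant to SMILES atom ordering", {
  variants <- c("CCO", "OCC", "C(O)C")
  cs <- compute_descriptors(compound_set_from_smiles(variants))
  for (d in c("mw", "clogp", "hbd", "hba", "tpsa")) {
    expect_equal(cs$table[[d]], rep(cs$table[[d]][1], 3), label = d)
  }
  fps <- ecfp_fingerprints(cs)
  expect_equal(tanimoto(fps[[1]], fps[[2]]), 1)
  expect_equal(tanimoto(fps[[1]], fps[[3]]), 1)
})

test_that("SDF and SMILES routes give identical descriptors", {
  cs1 <- compute_descriptors(compound_set_from_smiles(MBE1_SMILES, "m"))
  path <- withr::local_tempfile(fileext = ".sdf")
  ChemmineR::write.SDF(cs1$sdf, path)
  cs2 <- compute_descriptors(parse_structures(path))
  for (d in c("mw", "clogp", "hbd", "hba", "tpsa")) {
    expect_equal(cs2$table[[d]], cs1$table[[d]], label = d)
  }
})

test_that("lead compound passes its design thresholds", {
  ## optimal-profile windows: MW < 350, cLogP < 3.5, donors <= 2,
  ## TPSA < 120 (logP bounds kept loose: the method is tool-dependent)
  win <- list(mw = pc_window(upper = 350, upper_closed = FALSE),
              clogp = pc_window(upper = 3.5, upper_closed = FALSE),
              hbd = pc_window(upper = 2),
              tpsa = pc_window(upper = 120, upper_closed = FALSE))
  cs <- compute_descriptors(compound_set_from_smiles(MBE1_SMILES, "MBE1"))
  res <- apply_physchem_filter(cs, win)
  expect_equal(res$pass$id, "MBE1")
  expect_equal(nrow(res$fail), 0L)
})

test_that("physchem filter reports every violated descriptor", {
  tab <- data.frame(id = c("a", "b"), mw = c(500, 300),
                    clogp = c(2, 2), hbd = c(2, 2), hba = c(3, 3),
                    tpsa = c(150, 80))
  res <- apply_physchem_filter(tab, vhts_windows())
  expect_equal(res$fail$id, "a")
  expect_setequal(strsplit(res$fail$reasons, ",")[[1]], c("mw", "tpsa"))
  expect_equal(res$pass$id, "b")
  expect_error(apply_physchem_filter(tab[, 1:3], vhts_windows()),
               "not present")
})

test_that("physchem filter equals a brute-force per-descriptor scan", {
  set.seed(12)
  win <- vhts_windows()
  tab <- data.frame(id = sprintf("c%02d", 1:50),
                    mw = runif(50, 100, 600),
                    clogp = runif(50, -1, 6),
                    hbd = sample(0:6, 50, TRUE),
                    hba = sample(0:8, 50, TRUE),
                    tpsa = runif(50, 0, 200))
  res <- apply_physchem_filter(tab, win)
  oracle_pass <- with(tab, mw < 450 & clogp >= 1 & clogp <= 3 &
                        hbd >= 1 & hbd <= 3 & hba >= 1 & hba <= 5 &
                        tpsa < 140)
  expect_equal(res$pass$id, tab$id[oracle_pass])
  expect_equal(res$fail$id, tab$id[!oracle_pass])
})

test_that("combined rank is the minimum with deterministic ordering", {
  r <- data.frame(id = c("x", "y", "z", "w"),
                  hybrid_rank = c(5, 7, 9, NA),
                  moe_rank = c(12, 7, 2, 4))
  cr <- combine_ranks(r)
  expect_equal(cr$ranked$combined_rank,
               pmin(cr$ranked$hybrid_rank, cr$ranked$moe_rank))
  expect_equal(cr$ranked$id, c("z", "x", "y"))
  expect_equal(cr$excluded$id, "w")
  set.seed(8)
  rr <- data.frame(id = sprintf("m%03d", 1:60),
                   hybrid_rank = sample(1:500, 60),
                   moe_rank = sample(1:500, 60))
  got <- combine_ranks(rr)$ranked
  oracle <- rr
  oracle$combined_rank <- pmin(rr$hybrid_rank, rr$moe_rank)
  oracle <- oracle[order(oracle$combined_rank, oracle$hybrid_rank,
                         oracle$id), ]
  expect_equal(got$id, oracle$id)
  expect_error(combine_ranks(data.frame(id = "a", hybrid_rank = 0,
                                        moe_rank = 2)), "positive")
})

test_that("tanimoto matches a popcount oracle on random bit sets", {
  set.seed(33)
  nbits <- 256L
  for (trial in 1:20) {
    a <- sort(sample(0:(nbits - 1), sample(0:60, 1)))
    b <- sort(sample(0:(nbits - 1), sample(0:60, 1)))
    fa <- structure(as.integer(a), nbits = nbits)
    fb <- structure(as.integer(b), nbits = nbits)
    va <- integer(nbits); va[a + 1] <- 1L
    vb <- integer(nbits); vb[b + 1] <- 1L
    inter <- sum(va & vb)
    uni <- sum(va | vb)
    want <- if (uni == 0) 1 else inter / uni
    expect_equal(tanimoto(fa, fb), want)
  }
  expect_equal(tanimoto(structure(integer(0), nbits = 16L),
                        structure(integer(0), nbits = 16L)), 1)
  expect_error(tanimoto(structure(1L, nbits = 16L),
                        structure(1L, nbits = 32L)), "lengths differ")
})

test_that("diversity pick keeps the better-ranked of identical structures", {
  cs <- compound_set_from_smiles(c("CCO", "OCC", "c1ccccc1"),
                                 c("first", "dup", "ring"))
  fps <- ecfp_fingerprints(cs)
  kept <- diversity_pick(c("first", "dup", "ring"), fps)
  expect_equal(kept, c("first", "ring"))
  ## everything kept when all similarities are below the cutoff
  kept2 <- diversity_pick(c("first", "ring"), fps, sim_cutoff = 0.52)
  expect_equal(kept2, c("first", "ring"))
  expect_equal(diversity_pick(c("first", "dup", "ring"), fps,
                              max_picks = 1), "first")
})

test_that("no kept pair reaches the similarity cutoff (O(n^2) oracle)", {
  smis <- c("CCO", "CCCO", "CCCCO", "CCN", "CCCN", "c1ccccc1",
            "Cc1ccccc1", "CCc1ccccc1", "c1ccncc1", "Cc1ccncc1",
            "CC(=O)O", "CCC(=O)O", "CC(=O)N", "CC(=O)Nc1ccccc1",
            "Clc1ccccc1", "Brc1ccccc1", "OCC(O)CO", "C1CCCCC1",
            "C1CCNCC1", "CC(C)C(=O)O")
  cs <- compound_set_from_smiles(smis)
  fps <- ecfp_fingerprints(cs)
  for (cutoff in c(0.3, 0.52, 0.8)) {
    kept <- diversity_pick(names(fps), fps, sim_cutoff = cutoff)
    if (length(kept) > 1) {
      pairs <- combn(kept, 2)
      sims <- apply(pairs, 2, function(p)
        tanimoto(fps[[p[1]]], fps[[p[2]]]))
      expect_true(all(sims < cutoff))
    }
    ## greedy oracle recomputed independently
    oracle <- character(0)
    for (id in names(fps)) {
      if (all(vapply(oracle, function(k)
        tanimoto(fps[[id]], fps[[k]]) < cutoff, TRUE))) {
        oracle <- c(oracle, id)
      }
    }
    expect_equal(kept, oracle)
  }
})
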