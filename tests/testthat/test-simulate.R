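test_that("simulated OR genes are single-ORF, motif-bearing and seeded", {
  g <- simulate_or_gene(seed = 7)
  orf <- find_longest_orf(g[[1]])
  expect_gte(orf$length_nt, 900L)
  expect_equal(orf$length_nt, 930L)
  expect_equal(orf$start, 0L)
  expect_true(scan_or_motifs(orf_translation(g[[1]]))$all_present)
  # determinism
  expect_identical(simulate_or_gene(seed = 7), g)
  expect_false(identical(simulate_or_gene(seed = 8), g))
})

test_that("mutate_to_identity realizes the requested identity", {
  g <- simulate_or_gene(seed = 15)[[1]]
  same <- mutate_to_identity(g, 100, seed = 1)
  expect_equal(same$seq, g)
  expect_equal(same$realized_identity_pct, 100)
  m80 <- mutate_to_identity(g, 80, seed = 2)
  # direct recount of differing positions against the source
  diff <- sum(strsplit(g, "")[[1]] != strsplit(m80$seq, "")[[1]])
  recount <- 100 * (nchar(g) - diff) / nchar(g)
  expect_equal(m80$realized_identity_pct, recount)
  expect_true(abs(m80$realized_identity_pct - 80) <= 0.5)
  # different seeds, different sequences, both within tolerance
  m50a <- mutate_to_identity(g, 50, seed = 3)
  m50b <- mutate_to_identity(g, 50, seed = 4)
  expect_false(identical(m50a$seq, m50b$seq))
  expect_true(abs(m50a$realized_identity_pct - 50) <= 0.5)
  expect_error(mutate_to_identity(g, 0), "\\(0, 100\\]")
})

test_that("plant_gene inserts the stated fraction on the stated strand", {
  g <- simulate_or_gene(seed = 20)[[1]]
  genome <- simulate_genome(2000, seed = 21)
  full <- plant_gene(genome, g, 1, "+", seed = 22)
  expect_equal(full$truth$realized_coverage_pct, 100)
  expect_equal(nchar(full$genome[[1]]), 2000 + nchar(g))
  ins <- substr(full$genome[[1]], full$truth$insert_pos + 1,
                full$truth$insert_pos + nchar(g))
  expect_equal(ins, g)
  half <- plant_gene(genome, g, 0.5, "-", seed = 23)
  expect_equal(half$truth$fragment_nt, round(nchar(g) * 0.5))
  ins2 <- substr(half$genome[[1]], half$truth$insert_pos + 1,
                 half$truth$insert_pos + half$truth$fragment_nt)
  expect_equal(reverse_complement(ins2),
               substr(g, 1, half$truth$fragment_nt))
  expect_error(plant_gene(genome, g, 0), "\\(0, 1\\]")
  expect_error(plant_gene(genome, g, 1, "x"), "strand")
})

test_that("family simulation pairs every gene with one truth record", {
  fam <- simulate_or_family(n = 10, n_pseudo = 3, seed = 33)
  expect_equal(names(fam$genes), fam$truth$gene_id)
  expect_equal(sum(fam$truth$true_status == "pseudogene"), 3L)
  expect_identical(simulate_or_family(n = 10, n_pseudo = 3, seed = 33),
                   fam)
})

test_that("plate simulation is deterministic with complete truth", {
  ors <- sprintf("OR%d", 1:3)
  ods <- sprintf("od%d", 1:4)
  ag <- data.frame(or_name = "OR1", odorant = "od1", potency = "potent",
                   effect_AU = 9e5)
  a <- simulate_plate_dataset(ors, ods, ag, seed = 41)
  b <- simulate_plate_dataset(ors, ods, ag, seed = 41)
  expect_identical(a, b)
  # every OR x odorant pair has exactly one truth row
  expect_equal(nrow(a$truth), length(ors) * length(ods))
  expect_equal(anyDuplicated(a$truth[, c("or_name", "odorant")]), 0L)
  # truth potency derives from the generator's own saturation model
  tr <- a$truth[a$truth$or_name == "OR1" & a$truth$odorant == "od1", ]
  expect_true(tr$is_true_agonist)
  expect_equal(tr$true_potency_class, "high") # 0.6 * 9e5 > 3e5
  # one plate per odorant with QC rows for each
  expect_setequal(unique(a$wells$plate_id), paste0("plate_", ods))
  expect_equal(a$qc$plate_id, paste0("plate_", ods))
  expect_error(simulate_plate_dataset(ors, ods,
                                      data.frame(or_name = "OR1",
                                                 odorant = "od1",
                                                 potency = "potent",
                                                 effect_AU = -1)),
               "non-negative")
})

test_that("genome and FASTA emission are byte-stable under a seed", {
  g1 <- simulate_genome(500, seed = 77)
  g2 <- simulate_genome(500, seed = 77)
  expect_identical(g1, g2)
  p1 <- tempfile(fileext = ".fa"); p2 <- tempfile(fileext = ".fa")
  write_fasta(g1, p1, "dna"); write_fasta(g2, p2, "dna")
  expect_identical(readLines(p1), readLines(p2))
})
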