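test_that("protein abundance sums isoform-specific assigned peak volumes", {
  pep <- toy_peptides(c(10, 20, 30))
  expect_equal(abundance_norm_spec(pep, 6), 10)
  # no assigned peptides -> 0
  pep0 <- toy_peptides(c(10, 20), assigned = FALSE)
  expect_equal(abundance_norm_spec(pep0, 6), 0)
  # non-isoform-specific peptides are excluded from the sum
  extra <- rbind(toy_peptides(c(10, 20, 30)),
                 toy_peptides(100, specific = FALSE))
  expect_equal(abundance_norm_spec(extra, 6), 10)
  expect_error(abundance_norm_spec(pep, 0), "> 0")
  expect_error(peptide_table(data.frame(pv = -1)), "columns")
})

test_that("tetramer normalization pins the Kv4 core at four subunits", {
  tab <- data.frame(protein = c("Kv4.2", "Kv4.3", "KChIP4"),
                    abundance = c(1, 3, 2))
  n1 <- tetramer_normalize(tab)
  expect_equal(n1$normalized, c(1, 3, 2)) # factor 1: unchanged
  tab2 <- data.frame(protein = c("Kv4.2", "Kv4.3", "KChIP4"),
                     abundance = c(2, 6, 4))
  n2 <- tetramer_normalize(tab2)
  expect_equal(n2$normalized, c(1, 3, 2))
  expect_equal(sum(n2$normalized[n2$protein %in% c("Kv4.2", "Kv4.3")]), 4)
  # scale invariance: any positive rescaling gives the same normalized table
  for (c_ in c(0.01, 7, 1e4)) {
    tabc <- tab2; tabc$abundance <- tabc$abundance * c_
    expect_equal(tetramer_normalize(tabc)$normalized, n2$normalized)
  }
  # idempotence: normalizing the normalized abundances changes nothing
  again <- data.frame(protein = n2$protein, abundance = n2$normalized)
  expect_equal(tetramer_normalize(again)$normalized, n2$normalized)
  expect_error(tetramer_normalize(data.frame(protein = "KChIP1", abundance = 5)),
               "Kv4")
})

test_that("per-protein table applies the normalization across proteins", {
  pep <- rbind(toy_peptides(c(10, 20, 30), protein = "Kv4.3"),
               toy_peptides(c(4, 6), protein = "Kv4.2"),
               toy_peptides(c(8), protein = "KChIP4"))
  aa <- c(Kv4.3 = 6, Kv4.2 = 10, KChIP4 = 2)
  tab <- protein_abundance_table(pep, aa)
  expect_equal(tab$abundance[tab$protein == "Kv4.3"], 10)
  expect_equal(tab$abundance[tab$protein == "Kv4.2"], 1)
  expect_equal(tab$abundance[tab$protein == "KChIP4"], 4)
  norm <- tetramer_normalize(tab)
  expect_equal(sum(norm$normalized[norm$protein %in% c("Kv4.2", "Kv4.3")]), 4)
  expect_error(protein_abundance_table(pep, aa[1:2]), "missing accessible")
})

test_that("relative isoform abundance is max-normalized and control-referenced", {
  datasets <- paste0("d", 1:12)
  groups <- stats::setNames(rep(c("CTRL", "Ex3d"), each = 6), datasets)
  # identical peak volumes everywhere: both groups exactly 1
  prof_eq <- expand.grid(peptide = c("u1", "u2", "u3"), dataset = datasets)
  prof_eq$pv <- 500
  r_eq <- relative_isoform_abundance(prof_eq, groups)
  expect_equal(unname(r_eq$relative["CTRL"]), 1)
  expect_equal(unname(r_eq$relative["Ex3d"]), 1)
  # Ex3d at exactly 75% of control for every peptide -> ratio 0.75
  prof <- expand.grid(peptide = c("u1", "u2", "u3"), dataset = datasets,
                      stringsAsFactors = FALSE)
  base <- c(u1 = 200, u2 = 1000, u3 = 40)
  prof$pv <- base[prof$peptide] * ifelse(groups[prof$dataset] == "Ex3d", 0.75, 1)
  r <- relative_isoform_abundance(prof, groups)
  expect_equal(unname(r$relative["CTRL"]), 1)
  expect_equal(unname(r$relative["Ex3d"]), 0.75)
  expect_true(all(r$profiles$norm_pv >= 0 & r$profiles$norm_pv <= 1))
  # permutation invariance
  perm <- prof[sample.int(nrow(prof)), ]
  r2 <- relative_isoform_abundance(perm, groups)
  expect_equal(r2$relative, r$relative)
  # all-zero peptides are excluded with a warning
  prof0 <- rbind(prof, data.frame(peptide = "dead", dataset = datasets, pv = 0))
  expect_warning(r3 <- relative_isoform_abundance(prof0, groups), "all-zero")
  expect_equal(r3$relative, r$relative)
  expect_error(relative_isoform_abundance(prof, groups, ref = "WT"), "reference")
})
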