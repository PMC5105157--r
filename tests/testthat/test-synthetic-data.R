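test_that("sim_config validates probabilities and the mixture simplex", {
  mix <- c("30" = 0.6, "31" = 0.4)
  expect_s3_class(sim_config(1, 10, mix), "sim_config")
  expect_error(sim_config(1, 10, c(0.6, 0.4)), "named")
  expect_error(sim_config(1, 10, c("30" = 0.6, "31" = 0.5)), "sum to 1")
  expect_error(sim_config(1, 10, c("30" = 1.4, "31" = -0.4)), "nonnegative")
  expect_error(sim_config(1, 10, mix, damage_d1 = 1.2), "probabilities")
  expect_error(sim_config(1, 10, mix, damage_decay = 1), "damage_decay")
})

test_that("reference panel: one record per leaf, deterministic, distinguishable", {
  leaves <- tree_leaves(toy_tree)
  expect_equal(length(toy_panel$sequences), length(leaves))
  expect_equal(nrow(toy_panel$accessions), length(leaves))
  expect_setequal(toy_panel$accessions$taxid, leaves)
  expect_true(all(nchar(toy_panel$sequences) == 1000))
  again <- make_reference_panel(toy_tree, seq_len = 1000, seed = 101)
  expect_identical(toy_panel$sequences, again$sequences)
  # pairwise Hamming distance at least 10% of length
  s <- lapply(toy_panel$sequences, function(x) utf8ToInt(x))
  for (i in seq_along(s)) {
    for (j in seq_len(i - 1)) {
      expect_gte(sum(s[[i]] != s[[j]]), 100)
    }
  }
  expect_error(make_reference_panel(toy_tree, seq_len = 100), "seq_len")
})

test_that("congeneric references share an exact 50-mer (planted backbone)", {
  acc <- setNames(toy_panel$accessions$accession, toy_panel$accessions$taxid)
  a <- toy_panel$sequences[[acc[[as.character(tax_of[["Lepus arcticus"]])]]]]
  b <- toy_panel$sequences[[acc[[as.character(tax_of[["Lepus timidus"]])]]]]
  kmers_a <- substring(a, 1:(nchar(a) - 49), 50:nchar(a))
  shared <- vapply(kmers_a, function(k) grepl(k, b, fixed = TRUE), logical(1))
  expect_true(any(shared))
  # and a non-congeneric pair shares none
  c_ <- toy_panel$sequences[[acc[[as.character(tax_of[["Bos taurus"]])]]]]
  shared2 <- vapply(kmers_a, function(k) grepl(k, c_, fixed = TRUE), logical(1))
  expect_false(any(shared2))
})

test_that("empty and no-noise libraries behave exactly", {
  mix <- c("30" = 1)
  empty <- simulate_library(sim_config(5, 0, mix), toy_panel)
  expect_equal(nrow(empty$reads), 0)
  expect_equal(nrow(empty$truth), 0)

  clean <- simulate_library(
    sim_config(5, 300, mix, damage_d1 = 0, seq_error = 0,
               dup_frac = 0, lowcomplex_frac = 0),
    toy_panel
  )
  expect_equal(nrow(clean$reads), 300)
  ref <- toy_panel$sequences[[
    toy_panel$accessions$accession[toy_panel$accessions$taxid == 30]]]
  both <- paste(ref, revcomp(ref), sep = "NNN")
  expect_true(all(vapply(clean$reads$sequence, grepl, logical(1),
                         x = both, fixed = TRUE)))
  # truth rows agree with the planted coordinates
  tt <- clean$truth
  frag <- substring(ref, tt$ref_start, tt$ref_start + tt$read_len - 1)
  want <- ifelse(tt$strand == "-", revcomp(frag), frag)
  got <- clean$reads$sequence[match(tt$read_id, clean$reads$read_id)]
  expect_identical(unname(got), unname(want))
})

test_that("simulation is deterministic and rejects unknown taxa", {
  cfg <- sim_config(9, 500, c("30" = 0.5, "31" = 0.5))
  a <- simulate_library(cfg, toy_panel)
  b <- simulate_library(cfg, toy_panel)
  expect_identical(a, b)
  expect_error(
    simulate_library(sim_config(9, 10, c("12345" = 1)), toy_panel),
    "absent from panel"
  )
})

test_that("every non-contaminant read has exactly one truth row; fractions honoured", {
  sim <- shared_sim  # n = 1500, dup 0.1, lowcomplex 0.02
  n <- 1500
  expect_equal(nrow(sim$reads), n)
  expect_equal(nrow(sim$truth), n - round(0.02 * n))
  expect_equal(anyDuplicated(sim$truth$read_id), 0)
  non_contam <- sim$reads$read_id[!grepl("_lc_", sim$reads$read_id)]
  expect_setequal(non_contam, sim$truth$read_id)
  expect_equal(sum(sim$truth$is_duplicate), round(0.1 * n))
  expect_true(all(nchar(sim$reads$quality) == nchar(sim$reads$sequence)))
  expect_true(all(unique(strsplit(paste(sim$reads$quality, collapse = ""),
                                  "")[[1]]) == "F"))
  expect_true(all(sim$truth$read_len >= 25))
})

test_that("source mixture is recovered within 3 binomial SE", {
  mix <- c("30" = 0.5, "31" = 0.3, "39" = 0.2)
  sim <- simulate_library(
    sim_config(77, 8000, mix, dup_frac = 0, lowcomplex_frac = 0), toy_panel
  )
  emp <- table(sim$truth$source_taxid) / nrow(sim$truth)
  for (t in names(mix)) {
    p <- mix[[t]]
    se <- sqrt(p * (1 - p) / nrow(sim$truth))
    expect_lt(abs(emp[[t]] - p), 3 * se)
  }
})

test_that("realised 5' C->T rate matches the nominal rate and decays monotonically", {
  d1 <- 0.1
  sim <- simulate_library(
    sim_config(42, 20000, c("30" = 1), damage_d1 = d1, damage_decay = 0.5,
               seq_error = 0, dup_frac = 0, lowcomplex_frac = 0),
    toy_panel
  )
  tt <- sim$truth
  ref <- toy_panel$sequences[[
    toy_panel$accessions$accession[toy_panel$accessions$taxid == 30]]]
  # reconstruct the pre-damage fragment base at read position p
  rate_at <- function(p) {
    pos <- ifelse(tt$strand == "+", tt$ref_start + p - 1, tt$ref_start + tt$read_len - p)
    base <- substring(ref, pos, pos)
    base <- ifelse(tt$strand == "-", chartr("ACGT", "TGCA", base), base)
    wasC <- base == "C" & tt$read_len >= p
    hit <- vapply(tt$damaged_positions, function(x) p %in% x, logical(1))
    c(rate = mean(hit[wasC]), n = sum(wasC))
  }
  r1 <- rate_at(1)
  se <- sqrt(d1 * (1 - d1) / r1[["n"]])
  expect_lt(abs(r1[["rate"]] - d1), 3 * se)
  # geometric decay: non-increasing expected rate down the read
  rates <- vapply(1:4, function(p) rate_at(p)[["rate"]], numeric(1))
  expect_lt(rates[2], rates[1])
  expect_lt(rates[3], rates[2])
  r2_exp <- d1 * 0.5
  expect_lt(abs(rates[2] - r2_exp), 3 * sqrt(r2_exp * (1 - r2_exp) / rate_at(2)[["n"]]))
})

test_that("FASTQ round-trip preserves the library", {
  f <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(shared_sim$reads, f)
  back <- read_fastq(f)
  expect_equal(back, shared_sim$reads)
  empty <- simulate_library(sim_config(1, 0, c("30" = 1)), toy_panel)
  write_fastq(empty$reads, f)
  expect_equal(nrow(read_fastq(f)), 0)
})
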