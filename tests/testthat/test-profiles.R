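mk_asg <- function(taxids, library_id) {
  tibble::tibble(
    read_id = paste0(library_id, "_", seq_along(taxids)),
    taxid = taxids,
    rank = taxon_rank(toy_tree, taxids),
    name = taxon_name(toy_tree, taxids),
    n_tied_refs = 1L, unique = TRUE, library_id = library_id
  )
}

mk_meta <- function(ids, sites, layers, n = 1000) {
  tibble::tibble(library_id = ids, site = sites, layer = layers,
                 culture = NA_character_, library_type = "sediment",
                 n_reads_analysed = n)
}

test_that("merging layers sums counts and totals; unknown libraries error", {
  a1 <- mk_asg(rep(tax_of[["Bos taurus"]], 3), "L1")
  a2 <- mk_asg(c(rep(tax_of[["Bos taurus"]], 2), tax_of[["Ovis aries"]]), "L2")
  meta <- mk_meta(c("L1", "L2"), "Sandnes", "1")
  prof <- merge_layers(dplyr::bind_rows(a1, a2), meta)
  expect_equal(prof$count[prof$name == "Bos taurus"], 5L)
  expect_equal(prof$count[prof$name == "Ovis aries"], 1L)
  expect_equal(unique(prof$total_reads_analysed), 2000)
  # single library is the identity
  p1 <- merge_layers(a1, meta[1, ])
  expect_equal(p1$count, 3L)
  expect_error(merge_layers(mk_asg(30L, "LX"), meta), "LX")
})

test_that("merged profile is invariant to how reads are partitioned into libraries", {
  set.seed(41)
  taxids <- sample(c(tax_of[["Bos taurus"]], tax_of[["Ovis aries"]],
                     tax_of[["Capra hircus"]]), 300, TRUE)
  whole <- mk_asg(taxids, "ALL")
  merged_whole <- merge_layers(whole, mk_meta("ALL", "S", "1", 3000))
  for (k in c(2, 3)) {
    split_id <- sample(paste0("P", 1:k), 300, TRUE)
    parts <- whole
    parts$library_id <- split_id
    metas <- mk_meta(paste0("P", 1:k), "S", "1",
                     as.vector(table(split_id)[paste0("P", 1:k)]) * 10)
    merged_parts <- merge_layers(parts, metas)
    expect_equal(merged_parts$count[order(merged_parts$taxid)],
                 merged_whole$count[order(merged_whole$taxid)])
    expect_equal(sum(unique(merged_parts$total_reads_analysed)), 3000)
  }
})

test_that("named collapsing rules fold counts as published and conserve totals", {
  asg <- mk_asg(c(rep(tax_of[["Bovinae"]], 4), rep(tax_of[["Bos"]], 6)), "L1")
  prof <- merge_layers(asg, mk_meta("L1", "S", "1"))
  out <- collapse_taxa(prof, toy_tree)
  expect_equal(nrow(out), 1)
  expect_equal(out$name, "Bos")
  expect_equal(out$count, 10L)
  # Canis / C. lupus / familiaris all fold into C. lupus
  asg2 <- mk_asg(c(tax_of[["Canis"]], tax_of[["Canis lupus"]],
                   tax_of[["Canis lupus familiaris"]]), "L1")
  out2 <- collapse_taxa(merge_layers(asg2, mk_meta("L1", "S", "1")), toy_tree)
  expect_equal(out2$name, "Canis lupus")
  expect_equal(out2$count, 3L)
  # no applicable rule: unchanged
  asg3 <- mk_asg(rep(tax_of[["Vulpes lagopus"]], 2), "L1")
  prof3 <- merge_layers(asg3, mk_meta("L1", "S", "1"))
  expect_equal(collapse_taxa(prof3, toy_tree)$count, prof3$count)
  # conservation in all cases
  expect_equal(sum(out$count) + sum(out2$count), 13L)
})

test_that("automatic collapsing folds ancestors onto their unique nonzero species", {
  asg <- mk_asg(c(rep(tax_of[["Pagophilus groenlandicus"]], 8),
                  rep(tax_of[["Pagophilus"]], 2),
                  rep(tax_of[["Lepus"]], 3),
                  rep(tax_of[["Lepus arcticus"]], 2),
                  rep(tax_of[["Lepus timidus"]], 2)), "L1")
  prof <- merge_layers(asg, mk_meta("L1", "S", "1"))
  out <- collapse_taxa(prof, toy_tree, rules = list(), auto = TRUE)
  # Pagophilus genus reads join its only nonzero species
  expect_equal(out$count[out$name == "Pagophilus groenlandicus"], 10L)
  # Lepus stays: two nonzero species below it
  expect_equal(out$count[out$name == "Lepus"], 3L)
  expect_equal(sum(out$count), sum(prof$count))
})

test_that("relative abundance normalises within layers and flags empty subsets", {
  prof <- tibble::tibble(
    site = "S", layer = c("1", "1", "2", "2"),
    taxid = rep(c(tax_of[["Bos taurus"]], tax_of[["Ovis aries"]]), 2),
    name = rep(c("Bos taurus", "Ovis aries"), 2),
    rank = "species", count = c(75L, 25L, 10L, 30L),
    total_reads_analysed = 1000L
  )
  ra <- relative_abundance(prof)
  expect_equal(ra$fraction[ra$layer == "1"], c(0.75, 0.25))
  expect_equal(sum(ra$fraction[ra$layer == "2"]), 1)
  # scale invariance
  prof2 <- prof; prof2$count <- prof2$count * 7L
  expect_equal(relative_abundance(prof2)$fraction, ra$fraction)
  # zero subset
  prof3 <- prof; prof3$count <- 0L
  expect_warning(ra3 <- relative_abundance(prof3), "zero")
  expect_true(all(ra3$fraction == 0))
  # name-based subset
  sub <- relative_abundance(prof, taxa = "Bos taurus")
  expect_true(all(sub$fraction == 1))
})

test_that("vertebrate concentration implements reads-per-million exactly", {
  prof <- tibble::tibble(
    site = "S", layer = "1",
    taxid = c(tax_of[["Bos taurus"]], tax_of[["Taenia hydatigena"]]),
    name = c("Bos taurus", "Taenia hydatigena"),
    rank = "species", count = c(50L, 500L), total_reads_analysed = 1000000L
  )
  conc <- vertebrate_concentration(prof, toy_tree)
  expect_equal(conc$reads_per_million, 50)  # helminth reads don't count
  prof$count <- c(0L, 0L)
  expect_equal(vertebrate_concentration(prof, toy_tree)$reads_per_million, 0)
  # random formula oracle
  set.seed(42)
  for (i in 1:10) {
    n <- sample(1:20, 1)
    tax <- sample(toy_tree$nodes$taxid, n)
    p <- tibble::tibble(site = "S", layer = "1", taxid = tax,
                        name = taxon_name(toy_tree, tax),
                        rank = taxon_rank(toy_tree, tax),
                        count = sample(0:100, n, TRUE),
                        total_reads_analysed = sample(1e4:1e6, 1))
    vert <- is_within(toy_tree, p$taxid, "Vertebrata")
    want <- 1e6 * sum(p$count[vert]) / p$total_reads_analysed[1]
    expect_equal(vertebrate_concentration(p, toy_tree)$reads_per_million, want)
  }
})

test_that("rank tally counts distinct nodes per rank", {
  asg <- mk_asg(c(tax_of[["Bos taurus"]], tax_of[["Bos taurus"]],
                  tax_of[["Lepus"]], tax_of[["Canis lupus familiaris"]],
                  tax_of[["Odocoilinae"]]), "L1")
  tally <- rank_tally(asg)
  expect_equal(tally$n_taxa[tally$rank == "species"], 1L)
  expect_equal(tally$n_taxa[tally$rank == "genus"], 1L)
  expect_equal(tally$n_taxa[tally$rank == "subspecies"], 1L)
  expect_equal(tally$n_taxa[tally$rank == "subfamily"], 1L)
  expect_equal(nrow(rank_tally(asg[0, ])), 0)
  # set-cardinality oracle on random assignments
  set.seed(43)
  tax <- sample(toy_tree$nodes$taxid, 150, TRUE)
  rasg <- mk_asg(tax, "L1")
  tally2 <- rank_tally(rasg)
  want <- table(taxon_rank(toy_tree, unique(tax)))
  for (r in tally2$rank) expect_equal(tally2$n_taxa[tally2$rank == r],
                                      as.integer(want[[r]]))
})

test_that("top_species ranks species globally across layers", {
  asg1 <- mk_asg(c(rep(tax_of[["Bos taurus"]], 5), tax_of[["Ovis aries"]]), "L1")
  asg2 <- mk_asg(c(rep(tax_of[["Ovis aries"]], 2), rep(tax_of[["Mammalia"]], 9)), "L2")
  prof <- merge_layers(dplyr::bind_rows(asg1, asg2),
                       mk_meta(c("L1", "L2"), "S", c("1", "2")))
  top <- top_species(prof, toy_tree, n = 2)
  expect_equal(top[1], unname(tax_of[["Bos taurus"]]))   # 5 > 3
  expect_equal(top[2], unname(tax_of[["Ovis aries"]]))
  expect_length(top_species(prof, toy_tree, n = 1), 1)   # Mammalia never counts
})
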