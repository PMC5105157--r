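small_panel <- local({
  set.seed(21)
  s <- vapply(1:3, function(i)
    paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = ""), "")
  setNames(s, paste0("REF", 1:3))
})

test_that("planted substrings are found exactly, with and without substitutions", {
  ref <- small_panel[["REF2"]]
  read <- substr(ref, 101, 160)
  h <- exhaustive_align(tibble::tibble(read_id = "q", sequence = read),
                        small_panel, max_edit = 0)
  expect_true(any(h$ref_accession == "REF2" & h$ref_start == 101 &
                    h$edit_distance == 0 & h$strand == "+"))
  expect_true(all(h$cigar[h$edit_distance == 0] == "60M"))
  # one planted substitution -> minimal distance 1
  sub <- read
  substr(sub, 30, 30) <- setdiff(c("A", "C", "G", "T"), substr(read, 30, 30))[1]
  h1 <- exhaustive_align(tibble::tibble(read_id = "q", sequence = sub),
                         small_panel, max_edit = 3)
  expect_equal(min(h1$edit_distance[h1$ref_accession == "REF2"]), 1)
  # reverse-complement read maps on the minus strand at the same locus
  hrc <- exhaustive_align(tibble::tibble(read_id = "q", sequence = revcomp(read)),
                          small_panel, max_edit = 0)
  expect_true(any(hrc$strand == "-" & hrc$ref_start == 101))
})

test_that("minimal distances agree with the quadratic DP oracle on random reads", {
  set.seed(22)
  for (i in 1:15) {
    # mutate a planted fragment with substitutions and an occasional indel
    ref_i <- sample(3, 1)
    st <- sample(1:300, 1)
    rd <- substr(small_panel[[ref_i]], st, st + 39)
    if (i %% 3 == 0) {
      cut <- sample(5:35, 1)
      rd <- paste0(substr(rd, 1, cut - 1), substr(rd, cut + 1, 40))  # deletion
    }
    if (i %% 2 == 0) {
      p <- sample(nchar(rd), 1)
      substr(rd, p, p) <- sample(c("A", "C", "G", "T"), 1)
    }
    h <- exhaustive_align(tibble::tibble(read_id = "q", sequence = rd),
                          small_panel, max_edit = 6)
    for (acc in names(small_panel)) {
      want_f <- semiglobal_oracle(rd, small_panel[[acc]])
      want_r <- semiglobal_oracle(revcomp(rd), small_panel[[acc]])
      got <- h$edit_distance[h$ref_accession == acc]
      if (min(want_f, want_r) <= 6) {
        expect_equal(min(got), min(want_f, want_r))
      } else {
        expect_length(got, 0)
      }
    }
  }
})

test_that("max_edit = 0 finds exactly the exact-substring occurrences", {
  ref <- small_panel[["REF1"]]
  # a 12-mer short enough to recur is scanned against all start positions
  probe <- substr(ref, 50, 61)
  h <- exhaustive_align(tibble::tibble(read_id = "q", sequence = probe),
                        small_panel["REF1"], max_edit = 0)
  naive <- which(vapply(1:(nchar(ref) - 11), function(i)
    substr(ref, i, i + 11) == probe, logical(1)))
  naive_rc <- which(vapply(1:(nchar(ref) - 11), function(i)
    substr(ref, i, i + 11) == revcomp(probe), logical(1)))
  expect_setequal(h$ref_start[h$strand == "+"], naive)
  expect_setequal(h$ref_start[h$strand == "-"], naive_rc)
})

test_that("seeded and full-scan alignment strategies emit identical hit sets", {
  set.seed(28)
  refs <- setNames(vapply(1:3, function(i)
    paste(sample(c("A", "C", "G", "T"), 1500, TRUE), collapse = ""), ""),
    paste0("R", 1:3))
  mkread <- function(i) {
    if (i %% 5 == 0) {  # unrelated read: should hit nothing
      return(paste(sample(c("A", "C", "G", "T"), 40, TRUE), collapse = ""))
    }
    r <- sample(3, 1); st <- sample(1:1400, 1); L <- sample(25:90, 1)
    rd <- substr(refs[r], st, st + L - 1)
    if (i %% 2 == 0) { p <- sample(L, 1); substr(rd, p, p) <- sample(c("A", "C", "G", "T"), 1) }
    if (i %% 3 == 0) { p <- sample(5:(L - 5), 1); rd <- paste0(substr(rd, 1, p - 1), substr(rd, p + 1, L)) }
    if (i %% 4 == 0) rd <- revcomp(rd)
    rd
  }
  reads <- tibble::tibble(read_id = paste0("q", 1:150),
                          sequence = vapply(1:150, mkread, ""))
  ke <- as.integer(pmax(0L, floor(0.05 * nchar(reads$sequence))))
  a <- sedaprof:::semiglobal_align_cpp(reads$read_id, reads$sequence,
                                       names(refs), unname(refs), ke)
  b <- sedaprof:::semiglobal_align_full_cpp(reads$read_id, reads$sequence,
                                            names(refs), unname(refs), ke)
  key <- function(h) with(h, order(read_id, ref_accession, strand, ref_end))
  expect_equal(a[key(a), ], b[key(b), ], ignore_attr = TRUE)
  expect_gt(nrow(a), 0)
})

test_that("edit-distance filter boundary follows the 5% rule exactly", {
  hits <- tibble::tibble(
    read_id = c("a", "b", "c", "d"),
    ref_accession = "R", strand = "+", ref_start = 1L, ref_end = 1L,
    edit_distance = c(5L, 6L, 2L, 3L), cigar = "1M",
    read_len = c(100L, 100L, 40L, 40L)
  )
  kept <- edit_distance_filter(hits, 0.05)
  expect_setequal(kept$read_id, c("a", "c"))  # 5<=5, 2<=2; 6 and 3 dropped
  # random recomputation oracle
  set.seed(23)
  rh <- tibble::tibble(
    read_id = paste0("r", 1:200), ref_accession = "R", strand = "+",
    ref_start = 1L, ref_end = 1L,
    edit_distance = sample(0:8, 200, TRUE), cigar = "1M",
    read_len = sample(25:120, 200, TRUE)
  )
  expect_equal(nrow(edit_distance_filter(rh)),
               sum(rh$edit_distance <= 0.05 * rh$read_len))
})

test_that("best_hits keeps the minimal tie set, one row per reference", {
  hits <- tibble::tibble(
    read_id = "q",
    ref_accession = c("A", "B", "C", "A"),
    strand = "+",
    ref_start = c(10L, 5L, 7L, 40L), ref_end = c(20L, 15L, 17L, 50L),
    edit_distance = c(2L, 2L, 4L, 2L),
    cigar = "11M", read_len = 11L
  )
  bh <- best_hits(hits)
  expect_setequal(bh$ref_accession, c("A", "B"))
  expect_equal(bh$ref_start[bh$ref_accession == "A"], 10L)  # first placement
  single <- best_hits(hits[3, ])
  expect_equal(single$ref_accession, "C")
  # random min-filter oracle
  set.seed(24)
  rh <- tibble::tibble(
    read_id = sample(paste0("r", 1:20), 200, TRUE),
    ref_accession = sample(LETTERS[1:5], 200, TRUE),
    strand = "+", ref_start = sample(1:500, 200, TRUE),
    edit_distance = sample(0:4, 200, TRUE),
    cigar = "30M", read_len = 30L
  )
  rh$ref_end <- rh$ref_start + 29L
  bh <- best_hits(rh)
  mins <- tapply(rh$edit_distance, rh$read_id, min)
  expect_true(all(bh$edit_distance == mins[bh$read_id]))
  expect_equal(anyDuplicated(bh[, c("read_id", "ref_accession")]), 0)
})

test_that("filter-then-best equals best-then-filter when the global best survives", {
  sim <- simulate_library(
    sim_config(25, 400, c("30" = 0.5, "39" = 0.5), dup_frac = 0,
               lowcomplex_frac = 0),
    toy_panel
  )
  hits <- exhaustive_align(sim$reads, toy_panel)
  a <- best_hits(edit_distance_filter(hits))
  b <- edit_distance_filter(best_hits(hits))
  surviving <- intersect(a$read_id, b$read_id)
  a2 <- a[a$read_id %in% surviving, c("read_id", "ref_accession", "edit_distance")]
  b2 <- b[b$read_id %in% surviving, c("read_id", "ref_accession", "edit_distance")]
  expect_equal(dplyr::arrange(a2, read_id, ref_accession),
               dplyr::arrange(b2, read_id, ref_accession))
})

test_that("SAM round-trip preserves the hit set and unmapped/NM contracts hold", {
  sim <- simulate_library(
    sim_config(26, 150, c("30" = 0.6, "31" = 0.4), dup_frac = 0,
               lowcomplex_frac = 0),
    toy_panel
  )
  hits <- best_hits(edit_distance_filter(exhaustive_align(sim$reads, toy_panel)))
  f <- withr::local_tempfile(fileext = ".sam")
  write_sam(hits, toy_panel, f, reads = sim$reads)
  back <- read_sam(f)
  cols <- c("read_id", "ref_accession", "strand", "ref_start", "ref_end",
            "edit_distance", "cigar", "read_len")
  expect_equal(
    dplyr::arrange(back[cols], read_id, ref_accession),
    dplyr::arrange(hits[cols], read_id, ref_accession)
  )
  # unmapped records are skipped; a missing NM tag is a hard error
  lines <- readr::read_lines(f)
  writeLines(c(lines, "unmapped1\t4\t*\t0\t0\t*\t*\t0\t0\t*\t*"), f)
  expect_equal(nrow(read_sam(f)), nrow(hits))
  writeLines(c(lines[startsWith(lines, "@")],
               "nm_less\t0\tSYN0030.1\t5\t255\t30M\t*\t0\t0\t*\t*"), f)
  expect_error(read_sam(f), "nm_less")
})

test_that("samtools parses the SAM this package writes", {
  sim <- simulate_library(
    sim_config(27, 40, c("30" = 1), dup_frac = 0, lowcomplex_frac = 0),
    toy_panel
  )
  hits <- best_hits(edit_distance_filter(exhaustive_align(sim$reads, toy_panel)))
  f <- withr::local_tempfile(fileext = ".sam")
  write_sam(hits, toy_panel, f, reads = sim$reads)
  n <- as.integer(system2("samtools", c("view", "-c", f), stdout = TRUE))
  expect_equal(n, nrow(hits))
})
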