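# Synthetic-data generators: a toy arctic-midden taxonomy, a pseudo-random
# organelle reference panel, and a damaged ancient-read simulator with known
# ground truth. Everything downstream of sequencing is testable against the
# truth tables these emit.

#' Simulation configuration for an ancient sediment library
#'
#' Bundles and validates the generative parameters for [simulate_library()].
#'
#' @param seed Integer RNG seed.
#' @param n_reads Number of reads to emit (including duplicates and
#'   low-complexity contaminants).
#' @param mixture Named numeric vector: taxid -> proportion of template
#'   molecules; nonnegative, summing to 1.
#' @param frag_len_mean,frag_len_sd Fragment length distribution (nt), a
#'   normal truncated below at `frag_len_min`. Defaults 60 +/- 15 reflect
#'   typical post-collapse ancient-DNA fragment sizes.
#' @param frag_len_min Shortest emitted fragment; default 25 nt, the shortest
#'   read the downstream length filter retains.
#' @param damage_d1 Probability of a C->T misincorporation at 5' position 1,
#'   in `[0, 1]`. Terminal cytosine deamination is the ancient-DNA hallmark
#'   the damage module estimates.
#' @param damage_decay Per-position geometric decay of the damage probability
#'   (position p is hit with probability `damage_d1 * damage_decay^(p-1)`),
#'   in `(0, 1)`.
#' @param seq_error Per-base uniform sequencing error probability.
#' @param dup_frac Fraction of emitted reads that are exact (PCR) duplicates
#'   of other emitted reads.
#' @param lowcomplex_frac Fraction of emitted reads replaced by homopolymer or
#'   dinucleotide-repeat contaminants (no truth rows; the DUST filter should
#'   remove them).
#' @param damage_ga3 Optional mirrored 3' G->A damage probability; 0 (off) by
#'   default since the estimator quantifies the 5' C->T signal only.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(seed, n_reads, mixture,
                       frag_len_mean = 60, frag_len_sd = 15, frag_len_min = 25,
                       damage_d1 = 0.10, damage_decay = 0.5,
                       seq_error = 0.001, dup_frac = 0.10,
                       lowcomplex_frac = 0.02, damage_ga3 = 0) {
  stopifnot(length(n_reads) == 1, n_reads >= 0)
  mixture <- unlist(mixture)
  if (is.null(names(mixture)) || any(names(mixture) == "")) {
    stop("mixture must be a named vector: taxid -> proportion")
  }
  if (any(mixture < 0)) stop("mixture proportions must be nonnegative")
  if (abs(sum(mixture) - 1) > 1e-9) stop("mixture proportions must sum to 1")
  probs <- c(damage_d1 = damage_d1, seq_error = seq_error, dup_frac = dup_frac,
             lowcomplex_frac = lowcomplex_frac, damage_ga3 = damage_ga3)
  if (any(probs < 0 | probs > 1)) {
    stop("probabilities out of [0,1]: ",
         paste(names(probs)[probs < 0 | probs > 1], collapse = ", "))
  }
  if (damage_decay <= 0 || damage_decay >= 1) stop("damage_decay must be in (0,1)")
  stopifnot(frag_len_mean > 0, frag_len_sd >= 0, frag_len_min >= 1)
  structure(
    list(seed = as.integer(seed), n_reads = as.integer(n_reads),
         mixture = mixture, frag_len_mean = frag_len_mean,
         frag_len_sd = frag_len_sd, frag_len_min = frag_len_min,
         damage_d1 = damage_d1, damage_decay = damage_decay,
         seq_error = seq_error, dup_frac = dup_frac,
         lowcomplex_frac = lowcomplex_frac, damage_ga3 = damage_ga3),
    class = "sim_config"
  )
}

#' Toy arctic-midden taxonomy
#'
#' A fixed small tree in the shape of the NCBI taxonomy: arctic and Norse-farm
#' mammals (whales, seals, canids, livestock, caribou, hares) under
#' Vertebrata, plus the tapeworm (Taeniidae) and roundworm (Toxocaridae)
#' families whose host-specific species corroborate vertebrate identifications.
#' Genus *Lepus*, *Taenia* and *Toxocara* carry two species each so that
#' genuinely ambiguous read placements (and hence LCA assignments above
#' species) occur.
#'
#' @return A [taxonomy_tree()].
#' @export
make_toy_taxonomy <- function() {
  n <- function(taxid, parent, rank, name) tibble(taxid = taxid, parent = parent, rank = rank, name = name)
  nodes <- dplyr::bind_rows(
    n(1L, 1L, "no rank", "root"),
    n(2L, 1L, "kingdom", "Metazoa"),
    n(3L, 2L, "phylum", "Chordata"),
    n(4L, 3L, "no rank", "Vertebrata"),
    n(5L, 4L, "class", "Mammalia"),
    n(6L, 5L, "order", "Cetacea"),
    n(7L, 5L, "order", "Carnivora"),
    n(8L, 5L, "order", "Artiodactyla"),
    n(9L, 5L, "order", "Lagomorpha"),
    n(10L, 6L, "family", "Balaenidae"),
    n(11L, 7L, "family", "Phocidae"),
    n(12L, 7L, "family", "Canidae"),
    n(13L, 8L, "family", "Bovidae"),
    n(14L, 8L, "family", "Cervidae"),
    n(15L, 9L, "family", "Leporidae"),
    n(16L, 13L, "subfamily", "Bovinae"),
    n(17L, 14L, "subfamily", "Odocoilinae"),
    n(18L, 13L, "subfamily", "Caprinae"),
    n(20L, 10L, "genus", "Balaena"),
    n(21L, 11L, "genus", "Pagophilus"),
    n(22L, 11L, "genus", "Pusa"),
    n(23L, 12L, "genus", "Canis"),
    n(24L, 12L, "genus", "Vulpes"),
    n(25L, 16L, "genus", "Bos"),
    n(26L, 18L, "genus", "Ovis"),
    n(27L, 18L, "genus", "Capra"),
    n(28L, 17L, "genus", "Rangifer"),
    n(29L, 15L, "genus", "Lepus"),
    n(30L, 20L, "species", "Balaena mysticetus"),
    n(31L, 21L, "species", "Pagophilus groenlandicus"),
    n(32L, 22L, "species", "Pusa hispida"),
    n(33L, 23L, "species", "Canis lupus"),
    n(34L, 24L, "species", "Vulpes lagopus"),
    n(35L, 25L, "species", "Bos taurus"),
    n(36L, 26L, "species", "Ovis aries"),
    n(37L, 27L, "species", "Capra hircus"),
    n(38L, 28L, "species", "Rangifer tarandus"),
    n(39L, 29L, "species", "Lepus arcticus"),
    n(40L, 29L, "species", "Lepus timidus"),
    n(41L, 33L, "subspecies", "Canis lupus familiaris"),
    n(45L, 2L, "phylum", "Platyhelminthes"),
    n(46L, 45L, "class", "Cestoda"),
    n(47L, 46L, "order", "Cyclophyllidea"),
    n(48L, 47L, "family", "Taeniidae"),
    n(49L, 48L, "genus", "Taenia"),
    n(50L, 49L, "species", "Taenia hydatigena"),
    n(51L, 49L, "species", "Taenia multiceps"),
    n(52L, 48L, "genus", "Echinococcus"),
    n(53L, 52L, "species", "Echinococcus canadensis"),
    n(55L, 2L, "phylum", "Nematoda"),
    n(56L, 55L, "class", "Chromadorea"),
    n(57L, 56L, "order", "Ascaridida"),
    n(58L, 57L, "family", "Toxocaridae"),
    n(59L, 58L, "genus", "Toxocara"),
    n(60L, 59L, "species", "Toxocara canis"),
    n(61L, 59L, "species", "Toxocara cati")
  )
  taxonomy_tree(nodes)
}

#' Leaf taxa of a taxonomy tree
#'
#' @param tree A [taxonomy_tree()].
#' @return Integer vector of taxids that are not the parent of any other node.
#' @export
tree_leaves <- function(tree) {
  setdiff(tree$nodes$taxid, tree$nodes$parent[tree$nodes$parent != tree$nodes$taxid])
}

.random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Pseudo-random reference panel for a taxonomy
#'
#' One sequence per leaf (species or subspecies), standing in for the
#' mitochondrial genomes reads are classified against. Congeneric leaves share
#' an identical backbone spanning the first 30% of the sequence, so reads
#' drawn there match several references exactly and force genuine LCA
#' ambiguity; outside the backbone sequences are independent, keeping every
#' pair of references at a Hamming distance of at least 10% of their length.
#'
#' @param tree A [taxonomy_tree()].
#' @param seq_len Reference length in nucleotides (>= 200). The default,
#'   16000 nt, is mitogenome scale: shorter toy references inflate the rate
#'   of coincidental exact read duplicates (same locus, length and strand),
#'   which the duplicate-removal filter would then remove preferentially
#'   from abundant taxa. Tests that do not exercise deduplication biases can
#'   use shorter panels for speed.
#' @param seed Integer RNG seed; the same seed yields byte-identical output.
#' @param backbone_frac Fraction of sequence shared by congeners (default 0.3).
#' @return A `ref_panel` object: list with `sequences` (named character,
#'   accession -> sequence) and `accessions` (tibble: accession, taxid, name).
#' @export
make_reference_panel <- function(tree, seq_len = 16000, seed = 1,
                                 backbone_frac = 0.3) {
  stopifnot(seq_len >= 200)
  leaves <- tree_leaves(tree)
  if (length(leaves) == 0) stop("tree has no leaves")
  with_seed(seed, {
    # genus (nearest genus-ranked ancestor) of each leaf, NA if none
    genus_of <- vapply(leaves, function(t) {
      p <- root_path(tree, t)
      g <- p[taxon_rank(tree, p) == "genus"]
      if (length(g)) g[1] else NA_integer_
    }, integer(1))
    bb_len <- round(backbone_frac * seq_len)
    shared_genera <- unique(genus_of[!is.na(genus_of) & duplicated(genus_of)])
    backbones <- setNames(
      vapply(shared_genera, function(g) .random_dna(bb_len), ""),
      as.character(shared_genera)
    )
    seqs <- vapply(seq_along(leaves), function(i) {
      tail_seq <- .random_dna(seq_len - bb_len)
      g <- genus_of[i]
      head_seq <- if (!is.na(g) && as.character(g) %in% names(backbones)) {
        backbones[[as.character(g)]]
      } else {
        .random_dna(bb_len)
      }
      paste0(head_seq, tail_seq)
    }, "")
    acc <- sprintf("SYN%04d.1", leaves)
    names(seqs) <- acc
    # pairwise distinguishability outside shared backbones
    min_frac <- 0.10
    for (i in seq_along(seqs)) {
      for (j in seq_len(i - 1)) {
        ham <- sum(utf8ToInt(seqs[[i]]) != utf8ToInt(seqs[[j]]))
        if (ham < min_frac * seq_len) {
          stop("reference panel degenerate: sequences ", i, " and ", j,
               " differ at fewer than 10% of positions")
        }
      }
    }
    structure(
      list(
        sequences = seqs,
        accessions = tibble(accession = acc, taxid = leaves,
                            name = taxon_name(tree, leaves))
      ),
      class = "ref_panel"
    )
  })
}

#' @export
print.ref_panel <- function(x, ...) {
  cat("<ref_panel> ", length(x$sequences), " references of ",
      nchar(x$sequences[[1]]), " nt\n", sep = "")
  invisible(x)
}

# flip bases at given (read, position) pairs; `to` may be a fixed base or
# "random_other" for uniform choice among the three alternatives
.substitute_at <- function(seqs, idx, pos, to = "T") {
  if (length(idx) == 0) return(seqs)
  cur <- substr(seqs[idx], pos, pos)
  repl <- if (identical(to, "random_other")) {
    vapply(cur, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1), "",
           USE.NAMES = FALSE)
  } else {
    rep(to, length(idx))
  }
  substr(seqs[idx], pos, pos) <- repl
  seqs
}

#' Simulate a damaged ancient-DNA shotgun library
#'
#' Draws fragments from the reference panel according to the configured taxon
#' mixture, applies 5' terminal C->T deamination with geometric decay into the
#' fragment, adds uniform sequencing error, then emits a configurable fraction
#' of exact PCR duplicates and low-complexity contaminant reads. Every
#' non-contaminant read gets one row in the returned truth table.
#'
#' @param cfg A [sim_config()].
#' @param panel A [make_reference_panel()] result; every mixture taxid must
#'   have a reference in the panel.
#' @param prefix Read-name prefix (default `"read"`).
#' @return List with `reads` (tibble: read_id, sequence, quality) and `truth`
#'   (tibble: read_id, source_taxid, source_accession, ref_start, strand,
#'   read_len, damaged_positions list-column, is_duplicate).
#' @export
simulate_library <- function(cfg, panel, prefix = "read") {
  stopifnot(inherits(cfg, "sim_config"), inherits(panel, "ref_panel"))
  taxids <- as.integer(names(cfg$mixture))
  acc_of <- setNames(panel$accessions$accession, panel$accessions$taxid)
  missing <- setdiff(taxids, panel$accessions$taxid)
  if (length(missing)) {
    stop("mixture names taxid(s) absent from panel: ", paste(missing, collapse = ", "))
  }
  empty <- list(
    reads = tibble(read_id = character(), sequence = character(), quality = character()),
    truth = tibble(read_id = character(), source_taxid = integer(),
                   source_accession = character(), ref_start = integer(),
                   strand = character(), read_len = integer(),
                   damaged_positions = list(), is_duplicate = logical())
  )
  if (cfg$n_reads == 0) return(empty)

  with_seed(cfg$seed, {
    n <- cfg$n_reads
    n_lc <- round(cfg$lowcomplex_frac * n)
    n_dup <- round(cfg$dup_frac * n)
    n_src <- n - n_lc - n_dup
    if (n_src < 0) stop("dup_frac + lowcomplex_frac leave no source reads")

    ref_len <- nchar(panel$sequences[[1]])
    # fragment lengths: normal truncated to [frag_len_min, ref_len]
    lens <- integer(0)
    while (length(lens) < n_src) {
      cand <- round(rnorm(n_src, cfg$frag_len_mean, cfg$frag_len_sd))
      lens <- c(lens, cand[cand >= cfg$frag_len_min & cand <= ref_len])
    }
    lens <- lens[seq_len(n_src)]

    src_tax <- taxids[sample.int(length(taxids), n_src, replace = TRUE,
                                 prob = cfg$mixture)]
    src_acc <- unname(acc_of[as.character(src_tax)])
    starts <- floor(runif(n_src) * (ref_len - lens + 1)) + 1L
    strand <- sample(c("+", "-"), n_src, replace = TRUE)
    frag <- substr(panel$sequences[src_acc], starts, starts + lens - 1L)
    seqs <- ifelse(strand == "-", revcomp(frag), frag)

    # 5' C->T deamination, geometric decay into the fragment
    max_len <- max(lens)
    damaged <- vector("list", n_src)
    if (cfg$damage_d1 > 0) {
      for (p in seq_len(max_len)) {
        pr <- cfg$damage_d1 * cfg$damage_decay^(p - 1)
        if (pr < 1e-12) break
        isC <- substr(seqs, p, p) == "C" & lens >= p
        hit <- which(isC & runif(n_src) < pr)
        if (length(hit)) {
          seqs <- .substitute_at(seqs, hit, p, "T")
          for (i in hit) damaged[[i]] <- c(damaged[[i]], p)
        }
      }
    }
    # optional mirrored 3' G->A (off by default)
    if (cfg$damage_ga3 > 0) {
      for (p in seq_len(max_len)) {
        pr <- cfg$damage_ga3 * cfg$damage_decay^(p - 1)
        if (pr < 1e-12) break
        pos3 <- lens - p + 1L
        isG <- lens >= p & substr(seqs, pos3, pos3) == "G"
        hit <- which(isG & runif(n_src) < pr)
        for (i in hit) {
          substr(seqs[i], pos3[i], pos3[i]) <- "A"
          damaged[[i]] <- c(damaged[[i]], -p)
        }
      }
    }
    # uniform sequencing error
    if (cfg$seq_error > 0) {
      for (p in seq_len(max_len)) {
        hit <- which(lens >= p & runif(n_src) < cfg$seq_error)
        seqs <- .substitute_at(seqs, hit, p, "random_other")
      }
    }

    src_ids <- sprintf("%s_%06d", prefix, seq_len(n_src))
    truth <- tibble(
      read_id = src_ids, source_taxid = src_tax, source_accession = src_acc,
      ref_start = starts, strand = strand, read_len = lens,
      damaged_positions = lapply(damaged, function(x) as.integer(sort(x %||% integer(0)))),
      is_duplicate = FALSE
    )

    # exact PCR duplicates of already-emitted reads
    if (n_dup > 0 && n_src > 0) {
      of <- sample(n_src, n_dup, replace = TRUE)
      dup_ids <- sprintf("%s_dup_%06d", prefix, seq_len(n_dup))
      truth <- dplyr::bind_rows(truth, dplyr::mutate(
        truth[of, ], read_id = dup_ids, is_duplicate = TRUE
      ))
      seqs <- c(seqs, seqs[of])
      lens <- c(lens, lens[of])
      src_ids <- c(src_ids, dup_ids)
    }

    # low-complexity contaminants: homopolymers or dinucleotide repeats
    if (n_lc > 0) {
      lc_len <- pmax(cfg$frag_len_min,
                     round(rnorm(n_lc, cfg$frag_len_mean, cfg$frag_len_sd)))
      motifs <- c("A", "C", "G", "T", "AC", "AG", "AT", "CG", "CT", "GT")
      lc_seq <- vapply(seq_len(n_lc), function(i) {
        m <- sample(motifs, 1)
        substr(strrep(m, ceiling(lc_len[i] / nchar(m))), 1, lc_len[i])
      }, "")
      seqs <- c(seqs, lc_seq)
      lens <- c(lens, lc_len)
      src_ids <- c(src_ids, sprintf("%s_lc_%06d", prefix, seq_len(n_lc)))
    }

    ord <- sample(length(seqs))
    reads <- tibble(
      read_id = src_ids[ord],
      sequence = seqs[ord],
      quality = strrep("F", lens[ord])  # constant Q37
    )
    list(reads = reads, truth = truth)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
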