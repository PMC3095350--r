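# alignment filtering, junction-support counting, labelling, training
# selection, pool merging and summary accounting

test_that("quality and structure filters drop the right alignments", {
  aln <- make_alignments(
    blocks = list(rbind(c(20, 40), c(48, 70)),   # good spliced read
                  rbind(c(20, 40), c(48, 70)),   # identity below threshold
                  rbind(c(20, 47)),              # single exon, perfect
                  rbind(c(20, 40), c(25041, 25100)),  # 25,000-nt gap
                  rbind(c(20, 40), c(48, 70))),  # coverage below threshold
    identity = c(1, 0.94, 1, 1, 1),
    coverage = c(1, 1, 1, 1, 0.85))
  kept <- filter_alignments(aln, keep_reasons = TRUE)
  expect_equal(kept$read_id, "r001")
  rej <- attr(kept, "rejected")
  expect_equal(rej$reason[rej$read_id == "r002"], "low_identity")
  expect_equal(rej$reason[rej$read_id == "r003"], "single_exon")
  expect_equal(rej$reason[rej$read_id == "r004"], "oversized_intron")
  expect_equal(rej$reason[rej$read_id == "r005"], "low_coverage")

  # missing quality fields reject the alignment
  aln_na <- make_alignments(list(rbind(c(20, 40), c(48, 70))),
                            identity = NA_real_)
  expect_equal(nrow(filter_alignments(aln_na)), 0L)
})

test_that("junction support counts gap ends, not alignment termini", {
  fx <- tandem_fixture("+")
  genome <- read_genome(fx$genome)
  sites <- scan_nagnag_sites(extract_introns(fx$gff, fx$genome), genome)
  # proximal junction 47, distal 50: E reads gap 41-47, I reads gap 41-50
  e_block <- rbind(c(20, 40), c(48, 70))
  i_block <- rbind(c(20, 40), c(51, 80))
  aln <- make_alignments(c(rep(list(e_block), 3), rep(list(i_block), 2)))
  ev <- count_acceptor_support(sites, aln)
  expect_equal(ev$n_E, 3L)
  expect_equal(ev$n_I, 2L)

  # an alignment whose terminal block merely ends at the junction (within
  # the slack) contributes nothing, even though it has a genuine gap
  boundary <- make_alignments(list(rbind(c(15, 25), c(30, 47))),
                              read_id = "bnd")
  ev_b <- count_acceptor_support(sites, boundary)
  expect_equal(ev_b$n_E + ev_b$n_I, 0L)

  # each read counts once per site even with duplicated rows
  dup <- make_alignments(list(e_block, e_block), read_id = c("r1", "r1"))
  expect_equal(count_acceptor_support(sites, dup)$n_E, 1L)

  # 13 proximal + 27 distal planted reads recount exactly
  aln40 <- make_alignments(c(rep(list(e_block), 13), rep(list(i_block), 27)))
  ev40 <- count_acceptor_support(sites, aln40)
  expect_equal(c(ev40$n_E, ev40$n_I), c(13L, 27L))
  # brute-force oracle: compare every read's gap to the two junctions
  gaps <- vapply(aln40$blocks, function(m) m[2, 1] - 1L, integer(1))
  expect_equal(ev40$n_E, sum(gaps == sites$proximal_junction))
  expect_equal(ev40$n_I, sum(gaps == sites$distal_junction))
})

test_that("evidence counting matches per-read enumeration on simulation", {
  sim <- simulate_dataset(sim_config(seed = 310, n_genes = 12), tempfile())
  genome <- read_genome(sim$genome)
  sites <- scan_nagnag_sites(extract_introns(sim$annotation, genome), genome)
  aln <- filter_alignments(read_alignments_bed12(sim$alignments))
  ev <- count_acceptor_support(sites, aln)
  tt <- sim$truth_table
  m <- match(tt$site_id, ev$site_id)
  expect_equal(ev$n_E[m], tt$n_E_true)
  expect_equal(ev$n_I[m], tt$n_I_true)

  # relaxing the filters never decreases any count (monotonicity)
  aln_all <- read_alignments_bed12(sim$alignments)
  strict <- filter_alignments(aln_all, filter_params(0.99, 0.99, 5000))
  ev_strict <- count_acceptor_support(sites, strict)
  expect_true(all(ev$n_E >= ev_strict$n_E & ev$n_I >= ev_strict$n_I))
})

test_that("observed labels and training criteria follow the support rules", {
  counts <- make_counts(n_E = c(5, 13, 0, 10, 9, 18, 19, 0, 1),
                        n_I = c(0, 27, 0, 0, 0, 2, 2, 12, 1))
  lab <- label_sites(counts)
  expect_equal(lab$observed,
               c("E", "EI", "uncovered", "E", "E", "EI", "EI", "I", "EI"))
  sel <- select_training_set(lab)
  # (10,0) passes the constitutive rule, (9,0) does not; (18,2) has minor
  # fraction exactly 0.10, (19,2) falls just below at 0.095
  expect_equal(sel$training_class,
               c("none", "EI", "none", "E", "none", "EI", "none", "I",
                 "none"))
  expect_true(all(sel$training_class[sel$observed == "uncovered"] == "none"))
  expect_error(label_sites(make_counts(-1, 0)), "negative")
})

test_that("pool merging sums counts and can flip a label to EI", {
  a <- make_counts(c(1, 4, 0), c(0, 0, 0), site_id = c("s1", "s2", "s3"))
  a$n_E_sanger <- a$n_E; a$n_I_sanger <- a$n_I
  b <- make_counts(c(0, 0, 0), c(1, 0, 0), site_id = c("s1", "s2", "s3"))
  b$n_E_r454 <- b$n_E; b$n_I_r454 <- b$n_I
  m <- merge_evidence(a, b)
  expect_equal(m$n_E, c(1L, 4L, 0L))
  expect_equal(m$n_I, c(1L, 0L, 0L))
  expect_equal(label_sites(m)$observed, c("EI", "E", "uncovered"))
  # pool breakdown conserved
  expect_equal(m$n_E, m$n_E_sanger + m$n_E_r454)
  expect_equal(m$n_I, m$n_I_sanger + m$n_I_r454)
  expect_error(merge_evidence(a, make_counts(1, 1, site_id = "sX")),
               "different site_id")
})

test_that("summary accounting reproduces tally percentages", {
  n <- c(EI = 295L, E = 2695L, I = 2041L)
  counts <- make_counts(
    n_E = c(rep(1L, n["EI"]), rep(1L, n["E"]), rep(0L, n["I"])),
    n_I = c(rep(1L, n["EI"]), rep(0L, n["E"]), rep(1L, n["I"])))
  sites <- make_sites_stub(counts$site_id, rep("TAGTAG", nrow(counts)))
  s <- summarize_labels(label_sites(counts), sites)
  expect_equal(s$overall$covered, 5031L)
  expect_equal(unname(s$overall$pct["EI"]), 5.9)
  expect_equal(unname(s$overall$pct["E"]), 53.6)
  expect_equal(unname(s$overall$pct["I"]), 40.6)

  # GAG-containing subset: 149 alternative of 3225 covered GAG sites
  counts_g <- make_counts(n_E = c(rep(1L, 149), rep(1L, 3076)),
                          n_I = c(rep(1L, 149), rep(0L, 3076)))
  sites_g <- make_sites_stub(counts_g$site_id, rep("GAGCAG", 3225))
  sg <- summarize_labels(label_sites(counts_g), sites_g)
  expect_equal(unname(sg$gag$pct["EI"]), 4.6)

  # degenerate single-site table
  s1 <- summarize_labels(label_sites(make_counts(1, 0)),
                         make_sites_stub("s00001", "TAGTAG"))
  expect_equal(unname(s1$overall$pct["E"]), 100.0)
  expect_equal(s1$overall$covered, 1L)

  # conservation: covered = #E + #I + #EI
  expect_equal(s$overall$covered, sum(s$overall$counts))
})

test_that("evidence tables and alignment TSV dialect round-trip", {
  counts <- select_training_set(label_sites(
    make_counts(c(12, 0, 3), c(0, 5, 4))))
  counts$n_E_sanger <- counts$n_E
  counts$n_I_sanger <- counts$n_I
  path <- tempfile(fileext = ".tsv")
  write_evidence_tsv(counts, path)
  back <- read_evidence_tsv(path)
  expect_equal(as.data.frame(back), as.data.frame(counts))

  aln <- make_alignments(list(rbind(c(20, 40), c(48, 70)),
                              rbind(c(5, 15))),
                         identity = c(0.97, 1), coverage = c(0.95, 1))
  p2 <- tempfile(fileext = ".tsv")
  write_alignments_tsv(aln, p2)
  back2 <- read_alignments_tsv(p2)
  expect_equal(back2$read_id, aln$read_id)
  expect_equal(back2$blocks, unname(aln$blocks))
  expect_equal(back2$identity, aln$identity)
})

test_that("GFF3 match features parse into block structures", {
  gff <- c("##gff-version 3",
           paste("chr1", "est", "EST_match", "20", "70", ".", "+", ".",
                 "ID=readA;identity=0.97;coverage=0.96", sep = "\t"),
           paste("chr1", "est", "match_part", "20", "40", ".", "+", ".",
                 "Parent=readA", sep = "\t"),
           paste("chr1", "est", "match_part", "48", "70", ".", "+", ".",
                 "Parent=readA", sep = "\t"))
  path <- tempfile(fileext = ".gff3")
  writeLines(gff, path)
  aln <- read_alignments_gff3(path)
  expect_equal(nrow(aln), 1L)
  expect_equal(aln$blocks[[1]][, "start"], c(20L, 48L))
  expect_equal(aln$blocks[[1]][, "end"], c(40L, 70L))
  expect_equal(aln$identity, 0.97)
})
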