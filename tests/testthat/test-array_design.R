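# Hybrid-array design and simulated hierarchical assembly

test_that("building blocks are deterministic in the seed and free of enzyme sites", {
  b1 <- make_building_block(seed = 7)
  b2 <- make_building_block(seed = 7)
  expect_identical(b1$unit_sequence, b2$unit_sequence)
  expect_false(identical(make_building_block(seed = 8)$unit_sequence,
                         b1$unit_sequence))

  # no type-IIS recognition site (either strand) inside any block interior
  # or across a junction, over a spread of seeds
  sites <- c("GAAGAC", "GTCTTC", "GGTCTC", "GAGACC")
  for (s in 1:20) {
    b <- make_building_block(seed = s)
    ctx <- paste0(b$unit_sequence, b$unit_sequence)
    for (site in sites) expect_false(grepl(site, ctx, fixed = TRUE))
  }

  # spacers open with the fixed, determined dinucleotide
  expect_true(all(substr(b1$spacers, 1, 2) == "CA"))
})

test_that("ligating two blocks reconstitutes one full OL1 at the junction", {
  b <- make_building_block(seed = 1)
  ol1 <- b$ol1$sequence
  expect_identical(paste0(b$right_half_site, b$left_half_site), ol1)

  s <- initial_assembly_state(b)
  s2 <- simulate_assembly_cycle(s, s)
  expect_equal(s2$unit_count, 2L)
  expect_equal(s2$step_index, 2L)
  # raw 2-unit product holds exactly one complete internal OL1
  expect_equal(count_motifs(s2, b$ol1), 1L)

  # 2-unit + 2-unit sequence equals plain concatenation of unit sequences
  s4 <- simulate_assembly_cycle(s2, s2)
  expect_identical(s4$sequence,
                   paste(rep(b$unit_sequence, 4), collapse = ""))
})

test_that("raw n-unit ligation products carry n - 1 internal full OL1 sites", {
  b <- make_building_block(seed = 3)
  s <- initial_assembly_state(b)
  for (k in 1:3) {
    s <- simulate_assembly_cycle(s, s)
    expect_equal(count_motifs(s, b$ol1), s$unit_count - 1L)
    expect_equal(count_motifs(s, b$uas_motif), s$unit_count)
  }
})

test_that("overhang mismatches are rejected", {
  b <- make_building_block(seed = 1)
  s <- initial_assembly_state(b)
  bad <- s
  bad$left_overhang <- "AAAA"
  expect_error(simulate_assembly_cycle(s, bad), "overhang mismatch")
})

test_that("assembly obeys the doubling law: steps = 1 + log2(units)", {
  b <- make_building_block(seed = 2)
  for (n in 2^(0:8)) {
    arr <- assemble_to_target(b, n)
    expect_equal(arr$assembly_steps, 1L + as.integer(log2(n)))
    expect_equal(arr$n_units, n)
    expect_equal(arr$n_ol1, n)
    expect_equal(arr$n_uas, n)
  }
  expect_error(assemble_to_target(b, 48), "power of two")
  one <- assemble_to_target(b, 1)
  expect_equal(one$assembly_steps, 1L)
  expect_equal(one$n_ol1, 1L)
})

test_that("motif counting agrees with a naive sliding-window scan", {
  b <- make_building_block(seed = 5)
  arr <- assemble_to_target(b, 8)
  expect_equal(count_motifs(arr, b$ol1),
               naive_motif_count(arr$sequence, b$ol1$sequence))
  expect_equal(count_motifs(arr, b$uas_motif),
               naive_motif_count(arr$sequence, b$uas_motif$sequence))
  # reverse-complement occurrences are found too
  rc_arr <- paste(rev(strsplit(chartr("ACGT", "TGCA", arr$sequence),
                               "")[[1]]), collapse = "")
  expect_equal(count_motifs(rc_arr, b$ol1), arr$n_ol1)
})

test_that("identical seeds yield byte-identical finalized arrays", {
  a1 <- assemble_to_target(make_building_block(seed = 11), 16)
  a2 <- assemble_to_target(make_building_block(seed = 11), 16)
  expect_identical(a1$sequence, a2$sequence)
})

test_that("the reporter split partitions the mutated sequence", {
  spec <- reporter_split_spec()
  aa <- paste(c(rep("A", 151), "I", rep("G", 86)), collapse = "")
  frags <- split_reporter(spec, aa)
  expect_equal(nchar(frags$n_fragment), 154L)
  expect_equal(nchar(frags$c_fragment), 238L - 154L)
  # the I152L mutation lands in the N fragment
  expect_identical(substr(frags$n_fragment, 152, 152), "L")
  # reverting the mutation restores the original sequence exactly
  joined <- paste0(frags$n_fragment, frags$c_fragment)
  substr(joined, 152, 152) <- "I"
  expect_identical(joined, aa)

  expect_error(reporter_split_spec(split_after = 238), "split_after")
  expect_error(split_reporter(spec, paste(rep("A", 100), collapse = "")),
               "residues")
  expect_error(split_reporter(spec, paste(rep("A", 238), collapse = "")),
               "expected I")
})

test_that("FASTA and GenBank outputs round-trip the array sequence", {
  arr <- assemble_to_target(make_building_block(seed = 1), 4)
  fa <- tempfile(fileext = ".fasta")
  write_array_fasta(arr, fa)
  back <- Biostrings::readDNAStringSet(fa)
  expect_identical(as.character(back[[1]]), arr$sequence)

  gb <- tempfile(fileext = ".gb")
  write_array_genbank(arr, gb)
  lines <- readLines(gb)
  expect_true(any(grepl("^LOCUS", lines)))
  expect_true(any(grepl("ORIGIN", lines)))
  # one feature per motif occurrence
  expect_equal(sum(grepl("bound_moiety=\"OL1\"", lines)), arr$n_ol1)
  expect_equal(sum(grepl("bound_moiety=\"UAS\"", lines)), arr$n_uas)
  # sequence reassembles from the ORIGIN block
  ori <- lines[(which(lines == "ORIGIN") + 1):(length(lines) - 1)]
  seq <- toupper(gsub("[^acgt]", "", paste(ori, collapse = "")))
  expect_identical(seq, arr$sequence)
})
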