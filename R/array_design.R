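## Design and simulated hierarchical assembly of the hybrid OL1/UAS
## operator array, plus the split-reporter specification.
##
## The array is built from a single synthetic building block carrying a
## split lambda OL1 operator, a complete Gal4 UAS and flanking type-IIS
## recognition sites (BpiI, BsaI). Cutting outside the recognition site
## leaves compatible 4-nt overhangs, so ligating two inserts reconstitutes
## one full OL1 at the junction; iterating the digest/ligate cycle doubles
## the insert at every step.
##
## Coordinates are 1-based inclusive in all user-facing output; internal
## substring arithmetic uses base R `substr` (also 1-based).

#' Operator motif
#'
#' A named double-stranded DNA binding-site motif. For OL1 a split point
#' must be declared: the motif is partitioned into a 5' part of
#' `split_after` bases and a 3' part carrying the remainder, and the two
#' parts sit on adjacent building blocks so that ligation reconstitutes
#' the full site.
#'
#' @param name motif label, e.g. `"OL1"` or `"UAS"`.
#' @param sequence uppercase DNA string (ACGT only).
#' @param split_after optional 1-based index: the motif's 5' part ends at
#'   this base. Required for motifs used as split sites.
#' @return an object of class `operator_motif`.
#' @export
#' @examples
#' operator_motif("OL1", "TACCTCTGGCGGTGATA", split_after = 9)
operator_motif <- function(name, sequence, split_after = NULL) {
  stopifnot(is.character(name), nzchar(name))
  sequence <- toupper(sequence)
  if (!nzchar(sequence) || grepl("[^ACGT]", sequence)) {
    stop("motif sequence must be a nonempty string over A/C/G/T")
  }
  if (!is.null(split_after)) {
    split_after <- as.integer(split_after)
    if (split_after < 1 || split_after >= nchar(sequence)) {
      stop("split_after must lie strictly inside the motif")
    }
  }
  structure(
    list(name = name, sequence = sequence, split_after = split_after),
    class = "operator_motif"
  )
}

#' @export
print.operator_motif <- function(x, ...) {
  cat(sprintf("<operator_motif> %s  %s (%d bp%s)\n", x$name, x$sequence,
              nchar(x$sequence),
              if (is.null(x$split_after)) "" else
                sprintf(", split after %d", x$split_after)))
  invisible(x)
}

#' Default lambda OL1 operator motif
#'
#' The canonical 17-bp lambda cI operator OL1, split at the midpoint
#' (5' part = first 9 bases). The true array sequence of the published
#' construct is not public; this default is a standard placeholder and
#' can be replaced by any user-supplied [operator_motif()].
#' @return an `operator_motif`.
#' @export
default_ol1 <- function() {
  operator_motif("OL1", "TACCTCTGGCGGTGATA", split_after = 9L)
}

#' Default Gal4 UAS motif
#'
#' A 17-bp CGG-N11-CCG Gal4 upstream activating sequence consensus,
#' a placeholder for the unpublished construct sequence (see
#' [default_ol1()]).
#' @return an `operator_motif`.
#' @export
default_uas <- function() {
  operator_motif("UAS", "CGGAGGACTGTCCTCCG")
}

default_enzymes <- function() {
  c(BpiI = "GAAGAC", BsaI = "GGTCTC")
}

#' Design the initial array building block
#'
#' One block carries, left to right: the 3' part of the split OL1, a random
#' spacer, the full UAS, a second random spacer, and the 5' part of the
#' split OL1. Concatenating two blocks therefore reconstitutes one full OL1
#' at the junction (the block's `right_half_site`, at its right end, joined
#' to the next block's `left_half_site`). Each spacer starts with a fixed,
#' determined dinucleotide; the remaining spacer bases are random. Spacers
#' are resampled until no type-IIS recognition site (either strand) occurs
#' anywhere inside the block or across a block-block junction.
#'
#' @param ol1 an [operator_motif()] with a declared split point.
#' @param uas an [operator_motif()].
#' @param spacer_lengths integer vector of length 2: lengths of the two
#'   spacers (bases, including the fixed dinucleotide).
#' @param seed integer seed; blocks are deterministic given the seed.
#' @param fixed_dinucleotide the two determined bases opening each spacer.
#' @param enzymes named character vector of type-IIS recognition sequences.
#' @param max_tries resampling attempts before giving up.
#' @return an object of class `building_block` with fields
#'   `left_half_site`, `uas`, `right_half_site`, `spacers`,
#'   `left_overhang`, `right_overhang`, `enzyme_sites`, `unit_sequence`.
#' @export
#' @examples
#' b <- make_building_block(seed = 1)
#' nchar(b$unit_sequence)
make_building_block <- function(ol1 = default_ol1(), uas = default_uas(),
                                spacer_lengths = c(10L, 10L), seed = 1L,
                                fixed_dinucleotide = "CA",
                                enzymes = default_enzymes(),
                                max_tries = 200L) {
  if (is.null(ol1$split_after)) stop("ol1 must declare a split point")
  spacer_lengths <- as.integer(spacer_lengths)
  if (length(spacer_lengths) != 2 || any(spacer_lengths < 2)) {
    stop("spacer_lengths must be two integers >= 2 (room for the fixed dinucleotide)")
  }
  ol1_5p <- substr(ol1$sequence, 1L, ol1$split_after)            # block right end
  ol1_3p <- substr(ol1$sequence, ol1$split_after + 1L, nchar(ol1$sequence))
  forbidden <- unique(c(enzymes, vapply(enzymes, reverse_complement, "")))
  # enzyme sites must not fall inside the operator motifs themselves
  for (m in list(ol1, uas)) {
    if (any(vapply(forbidden, function(s) grepl(s, m$sequence, fixed = TRUE),
                   TRUE))) {
      stop(sprintf("motif %s contains a type-IIS recognition site", m$name))
    }
  }
  set.seed(seed)
  for (i in seq_len(max_tries)) {
    spacers <- vapply(spacer_lengths, function(n) {
      paste0(fixed_dinucleotide, random_dna(n - 2L))
    }, "")
    unit <- paste0(ol1_3p, spacers[[1]], uas$sequence, spacers[[2]], ol1_5p)
    # scan the unit and a simulated junction (unit||unit) for stray sites
    ctx <- paste0(unit, unit)
    if (!any(vapply(forbidden, function(s) grepl(s, ctx, fixed = TRUE), TRUE))) {
      overhang <- substr(ol1_3p, 1L, 4L)  # 4-nt scar spanning the OL1 split
      return(structure(
        list(
          left_half_site = ol1_3p,
          uas = uas$sequence,
          right_half_site = ol1_5p,
          spacers = spacers,
          left_overhang = overhang,
          right_overhang = overhang,
          enzyme_sites = enzymes,
          ol1 = ol1, uas_motif = uas,
          unit_sequence = unit,
          seed = as.integer(seed)
        ),
        class = "building_block"
      ))
    }
  }
  stop("could not sample spacers free of type-IIS recognition sites; ",
       "loosen spacer constraints or choose other enzymes")
}

#' @export
print.building_block <- function(x, ...) {
  cat(sprintf(
    "<building_block> %d bp unit: OL1-3' (%d) | spacer (%d) | UAS (%d) | spacer (%d) | OL1-5' (%d)\n",
    nchar(x$unit_sequence), nchar(x$left_half_site), nchar(x$spacers[[1]]),
    nchar(x$uas), nchar(x$spacers[[2]]), nchar(x$right_half_site)))
  cat(sprintf("  overhang %s; enzymes %s\n", x$left_overhang,
              paste(names(x$enzyme_sites), collapse = "/")))
  invisible(x)
}

#' Initial assembly state (one cloned building block)
#'
#' Represents the insert after the initial construction step: one unit,
#' step index 1.
#'
#' @param block a [make_building_block()] result.
#' @return an `assembly_state` with fields `unit_count`, `step_index`,
#'   `sequence`, `left_overhang`, `right_overhang`, `block`.
#' @export
initial_assembly_state <- function(block) {
  stopifnot(inherits(block, "building_block"))
  structure(
    list(unit_count = 1L, step_index = 1L, sequence = block$unit_sequence,
         left_overhang = block$left_overhang,
         right_overhang = block$right_overhang, block = block),
    class = "assembly_state"
  )
}

#' Simulate one digest-and-ligate doubling cycle
#'
#' Ligates two inserts cut with the two type-IIS enzymes. Their 4-nt
#' overhangs must match; the ligation joins the first state's right end to
#' the second state's left end, reconstituting one new full OL1 at the
#' junction. Unit counts add; the step counter advances by one.
#'
#' @param state,partner two `assembly_state` objects sharing a block design.
#' @return the ligated `assembly_state`.
#' @export
#' @examples
#' b <- make_building_block(seed = 1)
#' s <- initial_assembly_state(b)
#' simulate_assembly_cycle(s, s)$unit_count  # 2
simulate_assembly_cycle <- function(state, partner) {
  stopifnot(inherits(state, "assembly_state"),
            inherits(partner, "assembly_state"))
  if (!identical(state$right_overhang, partner$left_overhang)) {
    stop(sprintf("overhang mismatch: %s vs %s cannot be ligated",
                 state$right_overhang, partner$left_overhang))
  }
  joined <- paste0(state$sequence, partner$sequence)
  # the junction must read as one full OL1: right half-site then left half-site
  full_ol1 <- state$block$ol1$sequence
  n_r <- nchar(state$block$right_half_site)
  n_l <- nchar(state$block$left_half_site)
  junction <- substr(joined, nchar(state$sequence) - n_r + 1L,
                     nchar(state$sequence) + n_l)
  if (!identical(junction, full_ol1)) {
    stop("ligation junction does not reconstitute a full OL1 site")
  }
  structure(
    list(unit_count = state$unit_count + partner$unit_count,
         step_index = max(state$step_index, partner$step_index) + 1L,
         sequence = joined,
         left_overhang = state$left_overhang,
         right_overhang = partner$right_overhang,
         block = state$block),
    class = "assembly_state"
  )
}

#' Assemble a hybrid array of a target size by iterated doubling
#'
#' Runs the hierarchical scheme: one initial block-construction step, then
#' doubling cycles (self-ligation of the growing library) until
#' `target_units` units are concatenated, i.e. `1 + log2(target_units)`
#' steps in total. The raw n-unit ligation product carries n-1 internal
#' full OL1 sites plus one orphan half-site at each end; finalisation
#' appends the completing 3' half-site to the right flank so the emitted
#' array contains exactly n full OL1 (and n UAS) motifs.
#'
#' @param block a [make_building_block()] result.
#' @param target_units number of operator units; must be a power of two,
#'   since each cycle doubles the insert.
#' @return an object of class `hybrid_array` with fields `sequence`,
#'   `n_units`, `n_ol1`, `n_uas`, `assembly_steps`, `block`.
#' @export
#' @examples
#' arr <- assemble_to_target(make_building_block(seed = 1), 64)
#' arr$assembly_steps  # 7
assemble_to_target <- function(block, target_units) {
  stopifnot(inherits(block, "building_block"))
  target_units <- as.integer(target_units)
  if (target_units < 1 ||
      bitwAnd(target_units, target_units - 1L) != 0L) {
    stop("target_units must be a power of two: each digest/ligate cycle ",
         "doubles the insert, so only 1, 2, 4, 8, ... units are reachable")
  }
  state <- initial_assembly_state(block)
  while (state$unit_count < target_units) {
    state <- simulate_assembly_cycle(state, state)
  }
  finalize_array(state)
}

#' Finalise a raw ligation product into a complete hybrid array
#'
#' Appends the completing OL1 3' half-site to the right flank, so that the
#' terminal 5' half-site becomes a full OL1 and motif counts equal the
#' unit count.
#'
#' @param state an `assembly_state`.
#' @return a `hybrid_array`.
#' @export
finalize_array <- function(state) {
  stopifnot(inherits(state, "assembly_state"))
  block <- state$block
  seq <- paste0(state$sequence, block$left_half_site)
  arr <- structure(
    list(sequence = seq, n_units = state$unit_count,
         n_ol1 = NA_integer_, n_uas = NA_integer_,
         assembly_steps = state$step_index, block = block),
    class = "hybrid_array"
  )
  arr$n_ol1 <- count_motifs(arr, block$ol1)
  arr$n_uas <- count_motifs(arr, block$uas_motif)
  arr
}

#' @export
print.hybrid_array <- function(x, ...) {
  cat(sprintf(
    "<hybrid_array> %d units, %d bp; %d OL1 + %d UAS motifs; %d assembly steps\n",
    x$n_units, nchar(x$sequence), x$n_ol1, x$n_uas, x$assembly_steps))
  invisible(x)
}

#' Count motif occurrences in an array, both strands
#'
#' Counts occurrences of the motif in the array sequence and of its
#' reverse complement, via `Biostrings` pattern matching; positions found
#' on both strands (palindromes) are counted once.
#'
#' @param array a `hybrid_array`, `assembly_state`, or plain DNA string.
#' @param motif an [operator_motif()].
#' @return integer count.
#' @export
count_motifs <- function(array, motif) {
  seq <- if (is.character(array)) array else array$sequence
  stopifnot(inherits(motif, "operator_motif"))
  subj <- Biostrings::DNAString(seq)
  fwd <- Biostrings::matchPattern(motif$sequence, subj)
  rev <- Biostrings::matchPattern(reverse_complement(motif$sequence), subj)
  starts <- unique(c(BiocGenerics::start(fwd), BiocGenerics::start(rev)))
  length(starts)
}

#' Split-reporter specification
#'
#' Describes how a full-length fluorescent reporter is partitioned into an
#' N-terminal and a C-terminal fragment for bimolecular fluorescence
#' complementation, with optional point mutations applied before the
#' split. The default follows the mVenus split used in hybrid-array
#' labelling: residues 1-154 as the N fragment, 155-238 as the C fragment,
#' with I152L in the N fragment to suppress spontaneous self-assembly of
#' the halves.
#'
#' @param full_length reporter length in residues.
#' @param split_after 1-based residue index ending the N fragment.
#' @param mutations list of substitutions, each `list(pos=, from=, to=)`.
#' @return a `reporter_split_spec`.
#' @export
reporter_split_spec <- function(full_length = 238L, split_after = 154L,
                                mutations = list(list(pos = 152L,
                                                      from = "I", to = "L"))) {
  full_length <- as.integer(full_length)
  split_after <- as.integer(split_after)
  if (split_after < 1L || split_after >= full_length) {
    stop("split_after must satisfy 1 <= split_after < full_length")
  }
  for (m in mutations) {
    if (m$pos < 1L || m$pos > full_length) stop("mutation position out of range")
  }
  structure(list(full_length = full_length, split_after = split_after,
                 mutations = mutations),
            class = "reporter_split_spec")
}

#' Split a reporter protein sequence into its BiFC fragments
#'
#' Applies the specified point mutations, then partitions the sequence at
#' the split point. The two fragments are an exact partition of the
#' mutated sequence.
#'
#' @param spec a [reporter_split_spec()].
#' @param sequence protein sequence of length `spec$full_length`.
#' @return list with `n_fragment` and `c_fragment` character strings.
#' @export
#' @examples
#' seqaa <- paste(rep("A", 238), collapse = "")
#' substr(seqaa, 152, 152) <- "I"
#' frags <- split_reporter(reporter_split_spec(), seqaa)
#' nchar(frags$n_fragment)  # 154
split_reporter <- function(spec, sequence) {
  stopifnot(inherits(spec, "reporter_split_spec"), is.character(sequence))
  if (nchar(sequence) != spec$full_length) {
    stop(sprintf("sequence has %d residues; spec expects %d",
                 nchar(sequence), spec$full_length))
  }
  for (m in spec$mutations) {
    have <- substr(sequence, m$pos, m$pos)
    if (!identical(have, m$from)) {
      stop(sprintf("residue %d is %s, expected %s for mutation %s%d%s",
                   m$pos, have, m$from, m$from, m$pos, m$to))
    }
    substr(sequence, m$pos, m$pos) <- m$to
  }
  list(
    n_fragment = substr(sequence, 1L, spec$split_after),
    c_fragment = substr(sequence, spec$split_after + 1L, spec$full_length)
  )
}

#' Write a hybrid array as FASTA
#'
#' @param array a `hybrid_array`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_array_fasta <- function(array, path) {
  stopifnot(inherits(array, "hybrid_array"))
  s <- Biostrings::DNAStringSet(array$sequence)
  names(s) <- sprintf("hybrid_array_%dxOL1_%dxUAS", array$n_ol1, array$n_uas)
  Biostrings::writeXStringSet(s, filepath = path)
  invisible(path)
}

# 1-based start positions of motif occurrences on the given strand
motif_positions <- function(seq, pattern) {
  m <- Biostrings::matchPattern(pattern, Biostrings::DNAString(seq))
  BiocGenerics::start(m)
}

#' Write a hybrid array as a minimal GenBank flat file
#'
#' Emits LOCUS/FEATURES/ORIGIN records with one `protein_bind` feature per
#' OL1 and UAS occurrence (both strands), 1-based inclusive coordinates.
#'
#' @param array a `hybrid_array`.
#' @param path output file path.
#' @param locus_name LOCUS record name.
#' @return `path`, invisibly.
#' @export
write_array_genbank <- function(array, path, locus_name = "HYBRID_ARRAY") {
  stopifnot(inherits(array, "hybrid_array"))
  seq <- array$sequence
  n <- nchar(seq)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("LOCUS       %s %d bp    DNA     linear   SYN %s",
                     locus_name, n, format(Sys.Date(), "%d-%b-%Y")), con)
  writeLines(sprintf("DEFINITION  hybrid OL1/UAS operator array, %d units.",
                     array$n_units), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  feat <- function(label, from, to, strand) {
    loc <- sprintf("%d..%d", from, to)
    if (strand < 0) loc <- sprintf("complement(%s)", loc)
    writeLines(sprintf("     protein_bind    %s", loc), con)
    writeLines(sprintf("                     /bound_moiety=\"%s\"", label), con)
  }
  for (m in list(array$block$ol1, array$block$uas_motif)) {
    w <- nchar(m$sequence)
    for (p in motif_positions(seq, m$sequence)) feat(m$name, p, p + w - 1L, 1L)
    rc <- reverse_complement(m$sequence)
    if (!identical(rc, m$sequence)) {
      for (p in motif_positions(seq, rc)) feat(m$name, p, p + w - 1L, -1L)
    }
  }
  writeLines("ORIGIN", con)
  for (i in seq(1L, n, by = 60L)) {
    chunk <- substr(seq, i, min(i + 59L, n))
    groups <- substring(chunk, seq(1, nchar(chunk), 10),
                        pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    writeLines(sprintf("%9d %s", i, paste(tolower(groups), collapse = " ")), con)
  }
  writeLines("//", con)
  invisible(path)
}
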