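#' Junction sequence constants and fragment layout
#'
#' Single source of truth for the sequences that define a transposon-DNA
#' junction read in the Nextera-TruSeq hybrid library design. Read 1 of a
#' junction fragment begins with a variable balancer (3-6 nt), followed by
#' the 20-nt PCR anchor targeting the transposon, the 19-nt Tn5 mosaic end
#' (ME), and finally genomic sequence starting at the insertion site.
#'
#' The 19-nt ME is split by the two trimming rounds into its 5' 9-nt portion
#' (removed together with the anchor as one 29-nt pattern) and the remaining
#' 10-nt portion (removed exactly, no mismatches).
#'
#' @return A list with components:
#' \describe{
#'   \item{anchor20}{20-nt transposon-specific PCR anchor.}
#'   \item{me5}{5' 9-nt portion of the mosaic end.}
#'   \item{me10}{remaining 10-nt portion of the mosaic end.}
#'   \item{me19}{full 19-nt mosaic end, `me5` + `me10`.}
#'   \item{round1_pattern}{29-nt first-round trim pattern, `anchor20` + `me5`.}
#'   \item{balancer_len_range}{allowed balancer lengths, `c(3, 6)`.}
#'   \item{nextera_partial_len}{length of the partial Nextera i5 adapter in
#'     the first-PCR primer (34 bp).}
#'   \item{read_len}{sequencing read length (150 bp paired-end).}
#' }
#' @examples
#' lc <- layout_constants()
#' nchar(lc$round1_pattern)  # 29
#' @export
layout_constants <- function() {
  anchor20 <- "GCATGCAAGCTTCAGGGTTG"
  me5 <- "AGATGTGTA"
  me10 <- "TAAGAGACAG"
  list(
    anchor20 = anchor20,
    me5 = me5,
    me10 = me10,
    me19 = paste0(me5, me10),
    round1_pattern = paste0(anchor20, me5),
    balancer_len_range = c(3L, 6L),
    nextera_partial_len = 34L,
    read_len = 150L
  )
}

#' Specification for a synthetic transposon cassette
#'
#' @param total_len Total cassette length in bp (default 1221, the length of
#'   the KAN2 kanamycin-resistance cassette).
#' @param seed Integer seed controlling the random interior filler.
#' @return An object of class `cassette_spec`.
#' @export
cassette_spec <- function(total_len = 1221L, seed = 1L) {
  total_len <- as.integer(total_len)
  min_len <- 2L * 19L + 20L
  if (is.na(total_len) || total_len < min_len) {
    stop("total_len must be at least ", min_len,
         " bp (room for both mosaic ends and the anchor)")
  }
  structure(list(total_len = total_len, seed = as.integer(seed)),
            class = "cassette_spec")
}

#' Build a synthetic transposon cassette
#'
#' Constructs a deterministic (seeded) stand-in for the KAN2 transposon with
#' the correct length and terminal structure: the 5' terminus starts with the
#' reverse complement of the 19-nt mosaic end (so an amplification primer
#' beginning `CTGTCTCTTATACACATCT...` anneals there), and the 3' terminus --
#' the end read toward the genome -- ends with the 20-nt anchor followed by
#' the full mosaic end, so a junction read begins anchor + ME. The interior
#' is random filler at 50% GC with no homopolymer longer than 6.
#'
#' This is a synthetic cassette: only its length and termini matter to the
#' downstream junction workflow; the interior does not reproduce the vendor
#' KAN2 sequence.
#'
#' @param spec A [cassette_spec()].
#' @return A named character vector of length 1 (name `"KAN2_synthetic"`).
#' @examples
#' cas <- build_cassette(cassette_spec())
#' nchar(cas)  # 1221
#' @export
build_cassette <- function(spec = cassette_spec()) {
  stopifnot(inherits(spec, "cassette_spec"))
  lc <- layout_constants()
  left <- dna_revcomp(lc$me19)                # 19 nt
  right <- paste0(lc$anchor20, lc$me19)       # 39 nt, read-side terminus
  fill_len <- spec$total_len - nchar(left) - nchar(right)
  seq <- with_seed(spec$seed, {
    repeat {
      s <- paste0(left, random_dna(fill_len, max_homopolymer = 6L), right)
      # interior filler must not create a second read-side terminus
      if (length(gregexpr(right, s, fixed = TRUE)[[1]]) == 1L) break
    }
    s
  })
  setNames(seq, "KAN2_synthetic")
}

#' Split a first-PCR forward primer into its layout components
#'
#' The first-PCR transposon-specific primer has three parts: a partial
#' Nextera i5 adapter (34 bp), a balancer (3-6 bp) that staggers cluster
#' phasing to increase per-cycle nucleotide diversity, and the 20-bp anchor
#' targeting the transposon. The anchor must be the primer's 3' suffix.
#'
#' @param primer A DNA string.
#' @return A list with `nextera_part`, `balancer`, and `anchor`.
#' @examples
#' lc <- layout_constants()
#' p <- paste0(strrep("A", 34), "TAC", lc$anchor20)
#' primer_components(p)$balancer  # "TAC"
#' @export
primer_components <- function(primer) {
  lc <- layout_constants()
  primer <- toupper(primer)
  n <- nchar(primer)
  min_len <- lc$nextera_partial_len + lc$balancer_len_range[1] + nchar(lc$anchor20)
  if (n < min_len) stop("primer shorter than the minimal layout (", min_len, " nt)")
  if (substr(primer, n - nchar(lc$anchor20) + 1L, n) != lc$anchor20) {
    stop("layout error: primer does not end with the 20-nt anchor")
  }
  balancer <- substr(primer, lc$nextera_partial_len + 1L, n - nchar(lc$anchor20))
  bl <- nchar(balancer)
  if (bl < lc$balancer_len_range[1] || bl > lc$balancer_len_range[2]) {
    stop("layout error: balancer length ", bl, " outside [",
         lc$balancer_len_range[1], ", ", lc$balancer_len_range[2], "]")
  }
  list(
    nextera_part = substr(primer, 1L, lc$nextera_partial_len),
    balancer = balancer,
    anchor = lc$anchor20
  )
}

#' Transposome assembly mix
#'
#' Describes a transposome assembly reaction: transposon DNA mass and
#' concentration, Tn5 transposase concentration, and the volume ratio of Tn5
#' solution to DNA solution. Used to compute the Tn5-to-transposon molar
#' ratio and the maximal fraction of complete transposomes.
#'
#' @param dna_mass_ng Transposon DNA mass in the reaction (ng).
#' @param cassette_len_bp Transposon length (bp).
#' @param dna_conc_ng_per_ul DNA solution concentration (ng/uL).
#' @param tn5_conc_uM Tn5 transposase concentration (uM).
#' @param volume_ratio_tn5_to_dna Parts of Tn5 solution per part of DNA
#'   solution (e.g. 2 for a 1:2 DNA:Tn5 volume mix).
#' @param avg_bp_mass_da Average mass of one double-stranded base pair
#'   (g/mol); 650 is the standard approximation.
#' @return An object of class `transposome_mix`.
#' @export
transposome_mix <- function(dna_mass_ng, cassette_len_bp = 1221,
                            dna_conc_ng_per_ul, tn5_conc_uM = 1,
                            volume_ratio_tn5_to_dna = 2,
                            avg_bp_mass_da = 650) {
  vals <- c(dna_mass_ng, cassette_len_bp, dna_conc_ng_per_ul,
            tn5_conc_uM, volume_ratio_tn5_to_dna, avg_bp_mass_da)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all transposome mix quantities must be positive")
  }
  structure(list(
    dna_mass_ng = dna_mass_ng,
    cassette_len_bp = as.integer(cassette_len_bp),
    dna_conc_ng_per_ul = dna_conc_ng_per_ul,
    tn5_conc_uM = tn5_conc_uM,
    volume_ratio_tn5_to_dna = volume_ratio_tn5_to_dna,
    avg_bp_mass_da = avg_bp_mass_da
  ), class = "transposome_mix")
}

#' Tn5-to-transposon molar ratio of an assembly mix
#'
#' Transposon moles are `dna_mass_ng * 1e-9 / (cassette_len_bp *
#' avg_bp_mass_da)`. Tn5 moles follow from the pipetted volumes: the DNA
#' volume is `dna_mass_ng / dna_conc_ng_per_ul` uL, the Tn5 volume is that
#' times `volume_ratio_tn5_to_dna`, and uL x uM = 1e-12 mol.
#'
#' @param mix A [transposome_mix()].
#' @return The molar ratio Tn5 : transposon (a single number).
#' @examples
#' # 400 ng of a 1221-bp cassette at 100 ng/uL, mixed 1:2 with 1 uM Tn5
#' mix <- transposome_mix(400, 1221, 100, 1, 2)
#' molar_ratio(mix)  # ~15.9
#' @export
molar_ratio <- function(mix) {
  stopifnot(inherits(mix, "transposome_mix"))
  transposon_mol <- mix$dna_mass_ng * 1e-9 /
    (mix$cassette_len_bp * mix$avg_bp_mass_da)
  dna_vol_ul <- mix$dna_mass_ng / mix$dna_conc_ng_per_ul
  tn5_mol <- dna_vol_ul * mix$volume_ratio_tn5_to_dna * mix$tn5_conc_uM * 1e-12
  tn5_mol / transposon_mol
}

#' Maximal fraction of Tn5 in complete transposomes
#'
#' A complete transposome carries two Tn5 molecules per transposon molecule,
#' so at a Tn5:transposon molar ratio `r` at most `min(1, 2 / r)` of the Tn5
#' can reside in complete transposomes.
#'
#' @param ratio Tn5 : transposon molar ratio (> 0).
#' @return A fraction in (0, 1].
#' @export
complete_transposome_fraction <- function(ratio) {
  if (!is.numeric(ratio) || any(!is.finite(ratio)) || any(ratio <= 0)) {
    stop("ratio must be positive")
  }
  pmin(1, 2 / ratio)
}

#' Dump the layout constants as a table
#'
#' @return A data.frame with columns `name`, `length`, `sequence` (sequence
#'   is `NA` for numeric constants).
#' @export
layout_table <- function() {
  lc <- layout_constants()
  seqs <- c("anchor20", "me5", "me10", "me19", "round1_pattern")
  data.frame(
    name = c(seqs, "balancer_len_min", "balancer_len_max",
             "nextera_partial_len", "read_len"),
    length = c(vapply(lc[seqs], nchar, integer(1)),
               lc$balancer_len_range, lc$nextera_partial_len, lc$read_len),
    sequence = c(unlist(lc[seqs], use.names = FALSE), NA, NA, NA, NA),
    stringsAsFactors = FALSE
  )
}
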