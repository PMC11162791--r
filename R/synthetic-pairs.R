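# Synthetic stand-in paralog pairs. These are NOT the natural precursor
# sequences: they were constructed (by a constraint search, then frozen) to
# reproduce the documented geometry and statistics of the two pre-miRNA
# paralog families that motivate the toolkit, so that every worked example
# runs without restricted supplementary data.

SYN_PREMIR_A1 <- "GGGUCCUAUACGACGCUGUCAGGCUUAGCAUAGCCCUGACUUAGCGUCGUAUAGGACCCUAU"
SYN_PREMIR_A2 <- "GGGUCCUAUACGACGCUGUCAGCUUGCUCUUAUAUAAAUGCUGACACAGCGUCGUAUAGGACCCUAU"
SYN_DB_A1 <- paste0(strrep("(", 23), strrep(".", 11),
                    "))))))..", strrep(")", 17), "...")
SYN_DB_A2 <- paste0(strrep("(", 23), strrep(".", 16),
                    "))))))..", strrep(")", 17), "...")

SYN_PREMIR_B1 <- "CAGAACUCAAUCGCGUUCUCGCGCAGGAAUCUCGCGCGGAAGAACGCGAUUGAGUUCUGAUUAA"
SYN_PREMIR_B2 <- "CAGAACUCAAUCGCGUUCUCGCCUGUACCACUAAUAAAUCUAGGCGAGAACGCGAUUGAGUUCUG"
SYN_DB_B1 <- paste0(strrep("(", 24), strrep(".", 9),
                    ")))))..", strrep(")", 19), strrep(".", 5))
SYN_DB_B2 <- paste0(strrep("(", 24), strrep(".", 17), strrep(")", 24))

#' Synthetic paralog pre-miRNA pairs with the published worked-example
#' geometry
#'
#' Two built-in pairs of annotated hairpins that emulate, statistic by
#' statistic, the paralog families used to develop precursor-selective
#' ASO design. The sequences are synthetic (the natural worked-example
#' sequences live in restricted supplementary material); they were
#' engineered so that the toolkit's own measurements reproduce the
#' documented values:
#'
#' * family `"mir181"` (emulating X. laevis pre-miR-181a-1/-2): 62-nt and
#'   67-nt precursors; apical loops of 11 vs 16 nt; concatenated 51-nt
#'   stems identical at 47/51 positions (92%); loop composition 5/11 G/C
#'   (45.5%) for the first hairpin and 13/16 A/U (81%) for the second;
#'   identical mature 5p arms (positions 1-22); the 13-nt window spanning
#'   the 5p cleavage bond of one paralog differs from the other paralog by
#'   exactly 2 nt; the 25-nt 5p-side antisense target regions share 20/25
#'   identity (80%) and the 24-nt 3p-side regions 18/24 (75%); all four
#'   canonical oligomer targets hybridize below -21 kcal/mol, and the
#'   18-nt loop-covering oligomer of the second hairpin (only) is
#'   self-structured.
#' * family `"mir16"` (emulating human pre-miR-16-1/-2): 64-nt and 65-nt
#'   precursors with 9-nt vs 17-nt apical loops and identical 5p arms.
#'
#' @param family `"mir181"` or `"mir16"`.
#' @return A `paralog_fixture` list: `hairpin_a`, `hairpin_b`
#'   (annotated [parse_hairpin()] records with structures),
#'   `stem_identity`, `seed` (`NA`; the pair is fixed, not sampled).
#' @examples
#' pair <- synthetic_premir_pair("mir181")
#' iv_length(pair$hairpin_a$loop)  # 11
#' @export
synthetic_premir_pair <- function(family = c("mir181", "mir16")) {
  family <- match.arg(family)
  if (family == "mir181") {
    a <- parse_hairpin(SYN_PREMIR_A1, interval(0, 22), interval(40, 62),
                       name = "syn_preA_1", structure = SYN_DB_A1)
    b <- parse_hairpin(SYN_PREMIR_A2, interval(0, 22), interval(45, 67),
                       name = "syn_preA_2", structure = SYN_DB_A2)
  } else {
    a <- parse_hairpin(SYN_PREMIR_B1, interval(0, 22), interval(42, 64),
                       name = "syn_preB_1", structure = SYN_DB_B1)
    b <- parse_hairpin(SYN_PREMIR_B2, interval(0, 22), interval(43, 65),
                       name = "syn_preB_2", structure = SYN_DB_B2)
  }
  sa <- concat_stems(a); sb <- concat_stems(b)
  structure(list(hairpin_a = a, hairpin_b = b,
                 stem_identity = if (nchar(sa) == nchar(sb))
                   region_identity(sa, sb) else NULL,
                 seed = NA_integer_),
            class = "paralog_fixture")
}

#' Concatenated stem arms of a hairpin (everything outside the apical loop)
#'
#' The stem in the sense used for paralog identity statistics: the full
#' precursor minus the apical loop, bulges included.
#'
#' @param hairpin A `premirna_hairpin`.
#' @return Character scalar.
#' @export
concat_stems <- function(hairpin) {
  paste0(substr(hairpin$sequence, 1, hairpin$loop$start),
         substr(hairpin$sequence, hairpin$loop$end + 1L,
                nchar(hairpin$sequence)))
}

#' Synthetic morpholino-analog target regions and oligomers
#'
#' The four 24-25-nt morpholino-style antisense oligomers of the
#' `"mir181"` synthetic pair, used as the long-comparator chemistry in
#' selectivity statistics. Each MO targets one arm of one paralog plus
#' part of the apical loop: the 5p MOs (25 nt) share a target identity of
#' 20/25 between paralogs, the 3p MOs (24 nt) 18/24.
#'
#' @return Tibble: `name`, `arm`, `precursor`, `target_start`,
#'   `target_end` (1-based inclusive on the precursor), `target_site`,
#'   `sequence` (the antisense MO).
#' @export
synthetic_mo_oligos <- function() {
  pair <- synthetic_premir_pair("mir181")
  regions <- tibble::tribble(
    ~name, ~arm, ~precursor, ~s0, ~e0,
    "syn_MO_a1_5p", "5p", "syn_preA_1", 4L, 29L,
    "syn_MO_a2_5p", "5p", "syn_preA_2", 4L, 29L,
    "syn_MO_a1_3p", "3p", "syn_preA_1", 30L, 54L,
    "syn_MO_a2_3p", "3p", "syn_preA_2", 35L, 59L)
  seqs <- c(syn_preA_1 = pair$hairpin_a$sequence,
            syn_preA_2 = pair$hairpin_b$sequence)
  regions$target_site <- purrr::map2_chr(
    regions$precursor, seq_len(nrow(regions)),
    function(p, i) iv_subseq(seqs[[p]], interval(regions$s0[i], regions$e0[i])))
  tibble::tibble(name = regions$name, arm = regions$arm,
                 precursor = regions$precursor,
                 target_start = regions$s0 + 1L, target_end = regions$e0,
                 target_site = regions$target_site,
                 sequence = rna_revcomp(regions$target_site))
}
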