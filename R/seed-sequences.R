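# Bundled synthetic subfamily seed proteins.
#
# These are synthetic consensus-like aquaporin scaffolds, one per plant
# subfamily (PIP, TIP, NIP, SIP, XIP): six strongly hydrophobic 23-aa
# membrane-spanning blocks separated by hydrophilic loops, an NPA-type
# motif in loop B and loop E, and subfamily-typical ar/R selectivity-filter
# (H2, H5, LE1, LE2) and Froger (P1-P5) residues at annotated positions.
# They are NOT database records; they exist so that identification,
# classification and residue-extraction logic can be exercised and tested
# without downloading any genome. NPA variants follow the family pattern:
# NIP carries NPS and SIP carries NPT in the first motif.

.AQP_SEEDS <- list(
    PIP = list(
      sequence = "RDKSDPYGHNGNKYKLLILILLLLFIVFIIFVLVLLLIKSGDPTRTELFIFFFILVIVFIFLFLFILLLIKHRNPAYTDKYSNEPIIILIILILLIFVFFVVLIILLLPSPNNRPYTDELLFLFLLLLIVILLVVILVILLFNSNYTQYEQLFVLFIIIILIHIFLIIIILLLLQHQYNPASTSRRSARQTSVVIVLLLIILFIIVILFIIIVILTYYTWKRRRRTRKR",
      positions = c(NPA_LB = 74L, NPA_LE = 179L, H2 = 59L, H5 = 163L, LE1 = 183L, LE2 = 185L, P1 = 177L, P2 = 187L, P3 = 188L, P4 = 218L, P5 = 220L),
      tm_truth = cbind(start = c(16L, 48L, 86L, 120L, 152L, 193L), end = c(38L, 70L, 108L, 142L, 174L, 215L))
    ),
    TIP = list(
      sequence = "SSQQKSDSHNHHTTSLILLLFVLIFVILVLFLLFVIVIHGQEQDREGIIFFLFVVIIIHFLIVIILVLIIKDENPASQDGEQPGTFLLLLVVLVVLVILVILLILILLNPYKENSYTGDLVIVIIIVIVLVLVVFLILLIFFTSQNSYSHHILIIFVLVFLLIVILLFIILFLIKKTPNPAKAGVGSAPKRDVILVIIIIILFVLIIIIILVFLIENYGWRKPTRYGND",
      positions = c(NPA_LB = 74L, NPA_LE = 179L, H2 = 59L, H5 = 163L, LE1 = 183L, LE2 = 185L, P1 = 177L, P2 = 187L, P3 = 188L, P4 = 218L, P5 = 220L),
      tm_truth = cbind(start = c(16L, 48L, 86L, 120L, 152L, 193L), end = c(38L, 70L, 108L, 142L, 174L, 215L))
    ),
    NIP = list(
      sequence = "GRETTNGKYDDTQETVVVVIVLVIILIIVIIIILVVVIHHNRQKQGPFLVLIFIVLIVGLVIFVLVLILLNEHNPSSPNHDNRDGIFILFVVLLVVLLIFLFLLVFIITQKTHYHESHKIVIVLFIILLILLLLFILLLIIIPRKGEPERQVVIVILFIILLSIIFLFLLLILIKDFKNPAGGSRRSAQKPYVVIVFIFLVVIILLIIIIVIIFFHPYHINEDHERNTS",
      positions = c(NPA_LB = 74L, NPA_LE = 179L, H2 = 59L, H5 = 163L, LE1 = 183L, LE2 = 185L, P1 = 177L, P2 = 187L, P3 = 188L, P4 = 218L, P5 = 220L),
      tm_truth = cbind(start = c(16L, 48L, 86L, 120L, 152L, 193L), end = c(38L, 70L, 108L, 142L, 174L, 215L))
    ),
    SIP = list(
      sequence = "HTSPRHSEYPTHRQPLLFLLVILIILIILIVLVFLFFIDQEQDPQYQFIILILFVVLLALIIFLVIVIFLRTRNPTTYKSTNYNYVLVIVFFFLLLILLFVLLFFIIFTQYHSRYNPYNLIIFIIVFIIIIVLLLILFLLVVEDSYEPEEHIFLIFFLFVLIIIVIVFILLLLVRSIYNPAKGPSQAANYHEVVIIVLIVFVIFVFIFFIVLFIVQSYSWKPSSYHDRK",
      positions = c(NPA_LB = 74L, NPA_LE = 179L, H2 = 59L, H5 = 163L, LE1 = 183L, LE2 = 185L, P1 = 177L, P2 = 187L, P3 = 188L, P4 = 218L, P5 = 220L),
      tm_truth = cbind(start = c(16L, 48L, 86L, 120L, 152L, 193L), end = c(38L, 70L, 108L, 142L, 174L, 215L))
    ),
    XIP = list(
      sequence = "DKKHYSGESHENNDDVILLLILLFVFLIVLFFVIIIIFKDHKNETHRILVLFFLIIFVILLLFFIIVIILYYGNPAYPTQHNKPNLIFLLVVLIILILLFVVIILFVFKGENDRPDQHSFIIVFIILIILVLLIIFLLLILIHKQSKYRSGVVLLVIIILIVVLVIILLVFLIIDPVYNPAYAERDCASYKDVVILVLVFVLLIILVLLVLIIVLGKFTWNGKPSQDQQ",
      positions = c(NPA_LB = 74L, NPA_LE = 179L, H2 = 59L, H5 = 163L, LE1 = 183L, LE2 = 185L, P1 = 177L, P2 = 187L, P3 = 188L, P4 = 218L, P5 = 220L),
      tm_truth = cbind(start = c(16L, 48L, 86L, 120L, 152L, 193L), end = c(38L, 70L, 108L, 142L, 174L, 215L))
    )
)

#' Bundled synthetic subfamily seed proteins
#'
#' Returns the package's built-in aquaporin-like scaffold for each plant
#' subfamily, used as homology-search queries, classification references,
#' residue-extraction anchors and synthetic-genome templates.
#'
#' @param subfamily Optional subset of `c("PIP","TIP","NIP","SIP","XIP")`.
#' @return Named character vector of protein sequences.
#' @export
aqp_seed_proteins <- function(subfamily = names(.AQP_SEEDS)) {
  subfamily <- match.arg(subfamily, names(.AQP_SEEDS), several.ok = TRUE)
  vapply(.AQP_SEEDS[subfamily], `[[`, "", "sequence")
}

#' Residue-annotation anchor for a subfamily seed
#'
#' @param subfamily One of `"PIP"`, `"TIP"`, `"NIP"`, `"SIP"`, `"XIP"`.
#' @return A [reference_anchor()] whose positions mark the NPA motifs,
#'   ar/R filter and Froger residues of the seed.
#' @export
aqp_seed_anchor <- function(subfamily) {
  subfamily <- match.arg(subfamily, names(.AQP_SEEDS))
  s <- .AQP_SEEDS[[subfamily]]
  reference_anchor(paste0(subfamily, "_seed"), s$sequence, s$positions)
}

#' Planted transmembrane-segment coordinates of a subfamily seed
#' @param subfamily Subfamily name.
#' @return Integer matrix with columns `start`, `end` (six rows).
#' @export
aqp_seed_tm_truth <- function(subfamily) {
  subfamily <- match.arg(subfamily, names(.AQP_SEEDS))
  .AQP_SEEDS[[subfamily]]$tm_truth
}
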