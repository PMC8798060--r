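# Small fixtures built in code.

# 8-leaf tree with a 6-carrier ladder clade (MRCA at time 5) and two
# susceptible leaves that stay uncoalesced until time 7: at the carrier
# MRCA, k_S = 2.
nwk_ladder8 <- "((((((A:1,B:1):1,C:2):1,D:3):1,E:4):1,F:5):3,(G:7,H:7):1);"

# 6-leaf tree where carriers {A,B,C,D} have two lineages left at t = 3
# and the susceptibles {E,F} also have two.
nwk_balanced6 <- "(((A:1,B:1):3,(C:2,D:2):2):2,(E:5,F:5):1);"

# 3-leaf nesting example.
nwk_abc <- "((A:1,B:1):1,C:2);"

# Metadata table for a set of haplotype labels, two regions, one variant.
makeMeta <- function(labels, carriers, variant = "V1",
                     regions = rep(c("Ontario", "Midwest"),
                                   length.out = length(labels))) {
  ind <- rep(seq_len(ceiling(length(labels) / 2)), each = 2L)[
    seq_along(labels)]
  meta <- data.frame(haplotype_id = labels,
                     individual_id = paste0("I", ind),
                     population = paste0(regions, "_p1"),
                     region = regions, stringsAsFactors = FALSE)
  meta[[variant]] <- labels %in% carriers
  suppressWarnings(validateHaplotypeMetadata(meta))
}

# Dosage matrix matching the printed resistance survey margins: 152
# agricultural individuals, 80 carrying the codon-574 substitution, 48
# the codon-653 one, with an overlap of 16 individuals carrying both.
makeSurveyGenotypes <- function() {
  g <- matrix(0L, 152, 2, dimnames = list(NULL, c("Trp574Leu", "Ser653Asn")))
  g[1:80, "Trp574Leu"] <- 1L
  g[65:112, "Ser653Asn"] <- 1L   # 65..80 carry both (16 individuals)
  # give some carriers two copies so copy counts exceed carrier counts
  g[1:26, "Trp574Leu"] <- 2L
  g[81:91, "Ser653Asn"] <- 2L
  g
}

# Small random haplotype matrix with independent sites (LD-free null).
makeNullHaplotypeMatrix <- function(n_sites, n_haps, p = 0.4,
                                    chrom = "c1", spacing = 100,
                                    class = "missense") {
  g <- matrix(rbinom(n_sites * n_haps, 1L, p), n_sites, n_haps)
  haplotypeMatrix(g, data.frame(
    chrom = chrom, pos = seq(spacing, by = spacing, length.out = n_sites),
    ref = "A", alt = "T", class = class, stringsAsFactors = FALSE))
}
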