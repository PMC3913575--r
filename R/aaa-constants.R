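# Package-wide constants (loaded first).

# the 20 standard amino acids
.AA20 <- c("A","C","D","E","F","G","H","I","K","L",
           "M","N","P","Q","R","S","T","V","W","Y")

# synthetic-sequence alphabet: no Cys and no Gly at non-anchor positions,
# so the planted Cys anchor and W/F-G-x-G J motif stay unique
.SAFE_AA <- setdiff(.AA20, c("C", "G"))

# canonical Kabat-style CDR1/CDR2 offsets (0-based half-open) used both by
# the generator layout and as delineation defaults for full-length domains
.CDR_OFFSETS <- list(
  heavy = list(cdr1 = c(26L, 35L), cdr2 = c(49L, 65L)),
  kappa = list(cdr1 = c(23L, 34L), cdr2 = c(49L, 56L))
)

# J-segment FR4 anchor motifs per chain, and the concrete seed planted by
# the germline generator
.J_MOTIF <- c(heavy = "WG.G", kappa = "FG.G")
.J_SEED  <- c(heavy = "WGQG", kappa = "FGQG")

# Kyte-Doolittle residue hydropathy scale
.KYTE_DOOLITTLE <- c(
  A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
  L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2)
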