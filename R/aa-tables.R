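# Amino-acid lookup tables used by the bead-rotamer model.

#' @noRd
AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
         "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# side-chain heavy-atom counts (beyond the backbone)
AA_HEAVY <- c(A = 1, R = 7, N = 4, D = 4, C = 2, Q = 5, E = 5, G = 0, H = 6,
              I = 4, L = 4, K = 5, M = 4, F = 7, P = 3, S = 2, T = 3, W = 10,
              Y = 8, V = 3)

# Kyte-Doolittle hydropathy
AA_KD <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
           G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
           P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)

check_aa <- function(aa) {
  bad <- setdiff(unique(aa), AA1)
  if (length(bad) > 0)
    stop("unknown amino-acid code(s): ", paste(bad, collapse = ", "))
  invisible(aa)
}
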