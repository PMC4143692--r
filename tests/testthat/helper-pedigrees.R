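# fixture pedigrees used across the suite (built in code, no files)

trio_ped <- function() {
  pedigree(id = c("dad", "mom", "kid"),
           father = c("0", "0", "dad"), mother = c("0", "0", "mom"),
           sex = c(1, 2, 1))
}

# two parents, two children (full sibs)
nuclear_ped <- function(n_kids = 2L) {
  kids <- paste0("kid", seq_len(n_kids))
  pedigree(id = c("dad", "mom", kids),
           father = c("0", "0", rep("dad", n_kids)),
           mother = c("0", "0", rep("mom", n_kids)),
           sex = c(1, 2, rep_len(c(1, 2), n_kids)))
}

# one father, two mothers, one child each (half sibs)
halfsib_ped <- function() {
  pedigree(id = c("dad", "mom1", "mom2", "k1", "k2"),
           father = c("0", "0", "0", "dad", "dad"),
           mother = c("0", "0", "0", "mom1", "mom2"),
           sex = c(1, 2, 2, 1, 2))
}

# grandparents -> sibs a,b; each marries in; c1 and c2 are first cousins
cousin_ped <- function() {
  pedigree(id = c("gf", "gm", "a", "b", "sa", "sb", "c1", "c2"),
           father = c("0", "0", "gf", "gf", "0", "0", "a", "sb"),
           mother = c("0", "0", "gm", "gm", "0", "0", "sa", "b"),
           sex = c(1, 2, 1, 2, 2, 1, 1, 2))
}

# full-sib mating: child of s1 x s2 is inbred (self-kinship 0.625)
inbred_ped <- function() {
  pedigree(id = c("f", "m", "s1", "s2", "c"),
           father = c("0", "0", "f", "f", "s1"),
           mother = c("0", "0", "m", "m", "s2"),
           sex = c(1, 2, 1, 2, 1))
}

# 3-generation 8-person family: 4 founders, 4 non-founders, 8 meioses
threegen_ped <- function() {
  pedigree(id = c("gf", "gm", "s1", "s2", "c1", "c2", "g1", "g2"),
           father = c("0", "0", "0", "0", "gf", "gf", "c1", "s2"),
           mother = c("0", "0", "0", "0", "gm", "gm", "s1", "c2"),
           sex = c(1, 2, 2, 1, 1, 2, 1, 2))
}

# n unrelated singleton founders
singleton_ped <- function(n) {
  pedigree(id = sprintf("i%03d", seq_len(n)),
           father = rep("0", n), mother = rep("0", n),
           sex = rep_len(c(1, 2), n),
           fid = sprintf("S%03d", seq_len(n)))
}

# kinship oracle: average of ibd_matrix/4 over the full enumeration of
# inheritance vectors (independent of the recursion in kinship_matrix)
kinship_by_enumeration <- function(ped) {
  S <- enumerate_inheritance_vectors(ped)
  acc <- 0
  for (k in seq_len(nrow(S))) acc <- acc + ibd_matrix(ped, S[k, ])
  acc / (4 * nrow(S))
}

# residuals summing to zero, one value per pedigree member
centered_residuals <- function(ped, seed = 42L) {
  set.seed(seed)
  r <- stats::rnorm(length(ped$id))
  r <- r - mean(r)
  names(r) <- ped$id
  r
}
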