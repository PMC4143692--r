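#' Construct a validated pedigree
#'
#' Builds a \code{pedigree} object from parallel vectors describing family
#' membership and parentage, validates it, and stores individuals in
#' topological order (parents always precede their children).
#'
#' An individual must have either both parents in the pedigree or neither
#' (a founder). Founders are treated as non-inbred and mutually unrelated;
#' individuals in different families are unrelated by construction.
#' Pedigree loops (e.g. cousin matings recorded in the file) are permitted.
#'
#' @param id character vector of unique individual identifiers.
#' @param father,mother identifiers of each individual's parents; \code{"0"},
#'   \code{""} or \code{NA} denote a missing parent. Both must be present or
#'   both missing.
#' @param sex integer or character sex code: 1/\code{"M"} male, 2/\code{"F"}
#'   female, 0/\code{NA} unknown. Unknown sex is only allowed for individuals
#'   who are not themselves parents.
#' @param fid family identifiers; defaults to a single family \code{"F1"}.
#'
#' @return An object of class \code{pedigree}: a list with components
#'   \code{id}, \code{fid}, \code{sex} (0/1/2), integer parent indices
#'   \code{father} and \code{mother} (\code{NA} for founders), logical
#'   \code{founder}, and \code{nonfounders} (indices, topological order).
#'
#' @details Validation failures are signalled as classed conditions so
#'   callers can distinguish them: \code{gdtest_duplicate_id},
#'   \code{gdtest_single_parent}, \code{gdtest_unknown_parent},
#'   \code{gdtest_cycle}, \code{gdtest_parent_sex} (all inheriting from
#'   \code{gdtest_validation_error}).
#'
#' @seealso [read_pedigree()], [kinship_matrix()], [ibd_matrix()]
#' @export
#' @examples
#' ped <- pedigree(id = c("dad", "mom", "kid"),
#'                 father = c("0", "0", "dad"),
#'                 mother = c("0", "0", "mom"),
#'                 sex = c(1, 2, 1))
#' ped
pedigree <- function(id, father, mother, sex = NULL, fid = NULL) {
  id <- as.character(id)
  father <- as.character(father)
  mother <- as.character(mother)
  n <- length(id)
  if (is.null(fid)) fid <- rep("F1", n)
  fid <- as.character(fid)
  if (is.null(sex)) sex <- rep(0L, n)
  sex <- .parse_sex(sex)
  stopifnot(length(father) == n, length(mother) == n,
            length(sex) == n, length(fid) == n)

  missing_code <- function(x) is.na(x) | x == "0" | x == ""
  father[missing_code(father)] <- NA_character_
  mother[missing_code(mother)] <- NA_character_

  if (anyDuplicated(id)) {
    .ped_fail("gdtest_duplicate_id",
              sprintf("duplicate individual id(s): %s",
                      paste(unique(id[duplicated(id)]), collapse = ", ")))
  }
  one_parent <- xor(is.na(father), is.na(mother))
  if (any(one_parent)) {
    .ped_fail("gdtest_single_parent",
              sprintf("individual(s) with exactly one recorded parent: %s",
                      paste(id[one_parent], collapse = ", ")))
  }
  fi <- match(father, id)
  mi <- match(mother, id)
  bad <- (!is.na(father) & is.na(fi)) | (!is.na(mother) & is.na(mi))
  if (any(bad)) {
    .ped_fail("gdtest_unknown_parent",
              sprintf("parent id(s) not present in pedigree for: %s",
                      paste(id[bad], collapse = ", ")))
  }

  ord <- .topo_order(fi, mi, id)
  perm <- match(seq_len(n), ord)        # old index -> new position
  id <- id[ord]; fid <- fid[ord]; sex <- sex[ord]
  fi <- perm[fi[ord]]; mi <- perm[mi[ord]]

  # sex consistency of parents
  fathers <- unique(fi[!is.na(fi)])
  mothers <- unique(mi[!is.na(mi)])
  if (length(intersect(fathers, mothers))) {
    .ped_fail("gdtest_parent_sex",
              sprintf("individual(s) recorded as both father and mother: %s",
                      paste(id[intersect(fathers, mothers)], collapse = ", ")))
  }
  if (any(sex[fathers] != 1L)) {
    .ped_fail("gdtest_parent_sex",
              sprintf("father(s) not recorded as male: %s",
                      paste(id[fathers[sex[fathers] != 1L]], collapse = ", ")))
  }
  if (any(sex[mothers] != 2L)) {
    .ped_fail("gdtest_parent_sex",
              sprintf("mother(s) not recorded as female: %s",
                      paste(id[mothers[sex[mothers] != 2L]], collapse = ", ")))
  }

  founder <- is.na(fi)
  structure(list(id = id, fid = fid, sex = sex,
                 father = fi, mother = mi,
                 founder = founder,
                 nonfounders = which(!founder)),
            class = "pedigree")
}

.parse_sex <- function(sex) {
  if (is.character(sex)) {
    s <- toupper(sex)
    out <- ifelse(s %in% c("1", "M", "MALE"), 1L,
                  ifelse(s %in% c("2", "F", "FEMALE"), 2L, 0L))
  } else {
    out <- as.integer(sex)
    out[is.na(out) | !(out %in% 1:2)] <- 0L
  }
  out
}

.ped_fail <- function(class, msg) {
  stop(errorCondition(msg, class = c(class, "gdtest_validation_error",
                                     "error", "condition")))
}

# Kahn topological sort over the parent->child DAG; detects cycles
# (including self-parentage).
.topo_order <- function(fi, mi, id) {
  n <- length(id)
  indeg <- integer(n)
  kids <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(fi[i], mi[i])) {
      if (!is.na(p)) {
        if (p == i) .ped_fail("gdtest_cycle",
                              sprintf("individual %s is its own parent", id[i]))
        indeg[i] <- indeg[i] + 1L
        kids[[p]] <- c(kids[[p]], i)
      }
    }
  }
  queue <- which(indeg == 0L)
  ord <- integer(0)
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    ord <- c(ord, v)
    for (k in kids[[v]]) {
      indeg[k] <- indeg[k] - 1L
      if (indeg[k] == 0L) queue <- c(queue, k)
    }
  }
  if (length(ord) < n) {
    .ped_fail("gdtest_cycle",
              sprintf("pedigree contains a cycle involving: %s",
                      paste(id[setdiff(seq_len(n), ord)], collapse = ", ")))
  }
  ord
}

#' Read a pedigree from a PED/FAM-style file
#'
#' Reads the first five columns of a PLINK-style pedigree table
#' (family, individual, father, mother, sex), whitespace- or tab-delimited,
#' with \code{"0"} denoting a missing parent. Lines starting with \code{#}
#' are ignored.
#'
#' @param file path to the pedigree file, or a connection.
#' @return A validated [pedigree()] object in topological order.
#' @export
read_pedigree <- function(file) {
  tab <- utils::read.table(file, header = FALSE, comment.char = "#",
                           colClasses = "character",
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 5L)
    stop("pedigree file must have at least 5 columns: fid, id, father, mother, sex")
  pedigree(id = tab[[2L]], father = tab[[3L]], mother = tab[[4L]],
           sex = tab[[5L]], fid = tab[[1L]])
}

#' @export
print.pedigree <- function(x, ...) {
  cat(sprintf("pedigree: %d individuals in %d famil%s (%d founders, %d non-founders, %d meioses)\n",
              length(x$id), length(unique(x$fid)),
              if (length(unique(x$fid)) == 1L) "y" else "ies",
              sum(x$founder), length(x$nonfounders), n_meioses(x)))
  invisible(x)
}

#' @export
as.data.frame.pedigree <- function(x, ...) {
  data.frame(fid = x$fid, id = x$id,
             father = ifelse(is.na(x$father), "0", x$id[x$father]),
             mother = ifelse(is.na(x$mother), "0", x$id[x$mother]),
             sex = x$sex, stringsAsFactors = FALSE)
}

#' Number of meioses (inheritance-vector bits) in a pedigree
#'
#' Each non-founder contributes two meiosis bits: one for the gamete received
#' from the father and one for the gamete received from the mother.
#'
#' @param ped a [pedigree()].
#' @return integer, \code{2 * number of non-founders}.
#' @export
n_meioses <- function(ped) 2L * length(ped$nonfounders)

#' Kinship coefficient matrix
#'
#' Computes the matrix of kinship coefficients \eqn{\psi_{ij}} (the
#' probability that an allele drawn at random from individual i and one from
#' individual j are identical by descent) by the standard recursion over the
#' pedigree in topological order: founders have self-kinship 1/2 and are
#' mutually unrelated; for a non-founder i with parents f and m,
#' \eqn{\psi_{ii} = (1 + \psi_{fm})/2} and
#' \eqn{\psi_{ij} = (\psi_{fj} + \psi_{mj})/2} for any j that is not a
#' descendant of i. The expected allele-pair IBD count satisfies
#' \eqn{E[\phi_{ij}] = 4\psi_{ij}} over uniformly sampled inheritance vectors.
#'
#' @param ped a [pedigree()].
#' @return symmetric numeric matrix with individual ids as dimnames;
#'   block-diagonal across families.
#' @seealso [ibd_matrix()], [enumerate_inheritance_vectors()]
#' @export
#' @examples
#' trio <- pedigree(c("d","m","k"), c("0","0","d"), c("0","0","m"), c(1,2,1))
#' kinship_matrix(trio)["d","k"]   # parent-child: 0.25
kinship_matrix <- function(ped) {
  n <- length(ped$id)
  psi <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) {
    f <- ped$father[i]; m <- ped$mother[i]
    if (is.na(f)) {
      psi[i, i] <- 0.5
    } else {
      if (i > 1L) {
        j <- seq_len(i - 1L)
        psi[i, j] <- 0.5 * (psi[f, j] + psi[m, j])
        psi[j, i] <- psi[i, j]
      }
      psi[i, i] <- 0.5 * (1 + psi[f, m])
    }
  }
  psi
}

#' Sample a random inheritance vector
#'
#' Draws each meiosis bit as an independent fair Bernoulli variable: every
#' possible inheritance vector is equally likely, as in a gene-dropping
#' simulation at a marker unlinked to any causal locus.
#'
#' Bit ordering is canonical: non-founders in topological (pedigree) order,
#' the paternal-gamete bit before the maternal-gamete bit. A bit value of 0
#' means the transmitting parent passed its own paternal allele
#' (grandpaternal); 1 means its maternal allele.
#'
#' @param ped a [pedigree()].
#' @return integer vector of 0/1 of length [n_meioses()].
#' @export
sample_inheritance_vector <- function(ped) {
  as.integer(stats::runif(n_meioses(ped)) < 0.5)
}

#' Enumerate all inheritance vectors of a pedigree
#'
#' Produces every possible inheritance vector exactly once, in canonical bit
#' order (see [sample_inheritance_vector()]). Used as the exact oracle behind
#' identities such as \eqn{E[\Phi] = 4\Psi} and for exact conditional
#' variance computations on small pedigrees.
#'
#' @param ped a [pedigree()].
#' @param max_bits refuse to enumerate more than \code{2^max_bits} vectors
#'   (default 24 bits).
#' @return integer matrix with \code{2^n_meioses(ped)} rows, one inheritance
#'   vector per row.
#' @export
enumerate_inheritance_vectors <- function(ped, max_bits = 24L) {
  b <- n_meioses(ped)
  if (b > max_bits)
    stop(sprintf("pedigree has %d meiosis bits, above the enumeration cap of %d bits",
                 b, max_bits))
  .enumerate_bits(b)
}

# all 2^b binary vectors as rows, bit 1 varying slowest
.enumerate_bits <- function(b) {
  if (b == 0L) return(matrix(integer(0), nrow = 1L, ncol = 0L))
  m <- matrix(0L, nrow = 2L^b, ncol = b)
  for (j in seq_len(b)) {
    m[, j] <- rep(rep(c(0L, 1L), each = 2L^(b - j)), length.out = 2L^b)
  }
  m
}

#' Founder-allele labels under an inheritance vector
#'
#' Assigns the \code{2 * n_founders} distinct founder-allele labels and
#' propagates them down the pedigree along the inheritance vector \code{s}:
#' each non-founder's paternal (maternal) label is a copy of the father's
#' (mother's) paternal or maternal label, selected by the corresponding
#' meiosis bit. Two allele slots are identical by descent exactly when they
#' carry the same label.
#'
#' @param ped a [pedigree()].
#' @param s integer inheritance vector from [sample_inheritance_vector()] or
#'   a row of [enumerate_inheritance_vectors()].
#' @return integer matrix with one row per individual and columns
#'   \code{paternal}, \code{maternal} holding founder-allele labels in
#'   \code{1:(2*n_founders)}.
#' @export
allele_labels <- function(ped, s) {
  n <- length(ped$id)
  if (length(s) != n_meioses(ped))
    stop("inheritance vector length does not match the pedigree")
  lab <- matrix(0L, n, 2L, dimnames = list(ped$id, c("paternal", "maternal")))
  next_label <- 1L
  bit <- 1L
  for (i in seq_len(n)) {
    if (ped$founder[i]) {
      lab[i, ] <- c(next_label, next_label + 1L)
      next_label <- next_label + 2L
    } else {
      lab[i, 1L] <- lab[ped$father[i], 1L + s[bit]]
      lab[i, 2L] <- lab[ped$mother[i], 1L + s[bit + 1L]]
      bit <- bit + 2L
    }
  }
  lab
}

#' IBD allele-pair count matrix for a fixed inheritance vector
#'
#' For individuals i and j, \eqn{\phi_{ij}} counts how many of the four
#' allele pairs (paternal-paternal, paternal-maternal, maternal-paternal,
#' maternal-maternal) are identical by descent under the inheritance vector
#' \code{s}. The diagonal is 2 for non-inbred individuals and \code{2 + 2F}
#' under inbreeding. Averaged over all inheritance vectors the matrix equals
#' \code{4 * kinship_matrix(ped)}.
#'
#' @param ped a [pedigree()].
#' @param s integer inheritance vector.
#' @return symmetric integer matrix with entries in 0..4, zero across
#'   families.
#' @seealso [kinship_matrix()], [allele_labels()]
#' @export
ibd_matrix <- function(ped, s) {
  lab <- allele_labels(ped, s)
  p <- lab[, 1L]; m <- lab[, 2L]
  phi <- outer(p, p, "==") + outer(p, m, "==") +
    outer(m, p, "==") + outer(m, m, "==")
  storage.mode(phi) <- "integer"
  dimnames(phi) <- list(ped$id, ped$id)
  phi
}
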