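## Independent brute-force oracles used across the suite.  These stay
## deliberately naive (explicit double loops) so they are independent of
## the vectorised implementation paths they check.

## total mock energy: full double loop over unique pairs
brute_mock_total <- function(elements, coords, table = NULL) {
  n <- length(elements)
  s <- 0
  if (n < 2L) return(0)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      r <- sqrt(sum((coords[i, ] - coords[j, ])^2))
      s <- s + mock_pair_potential(elements[i], elements[j], r, table)
    }
  }
  s
}

## cross-group pair sum: for a pairwise potential this equals the
## interaction energy E(AuB) - E(A) - E(B) exactly
brute_mock_cross <- function(sub_a, sub_b, table = NULL) {
  s <- 0
  for (i in seq_along(sub_a$elements)) {
    for (j in seq_along(sub_b$elements)) {
      r <- sqrt(sum((sub_a$coords[i, ] - sub_b$coords[j, ])^2))
      s <- s + mock_pair_potential(sub_a$elements[i], sub_b$elements[j], r, table)
    }
  }
  s
}

## waters within cutoff by explicit all-pairs distances
brute_waters_within <- function(frame, solute_serials, cutoff) {
  atoms <- frame$atoms
  solute_pos <- match(solute_serials, atoms$serial)
  water_rows <- which(atoms$residue_name %in% c("HOH", "SOL", "WAT", "TIP3"))
  kept <- integer(0)
  for (m in unique(atoms$mol_id[water_rows])) {
    rows <- water_rows[atoms$mol_id[water_rows] == m]
    dmin <- Inf
    for (i in rows) {
      for (j in solute_pos) {
        d <- sqrt(sum((frame$coords[i, ] - frame$coords[j, ])^2))
        if (d < dmin) dmin <- d
      }
    }
    if (dmin <= cutoff) kept <- c(kept, m)
  }
  sort(kept)
}

## random rigid rotation matrix (QR of a Gaussian matrix, det +1)
random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}
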