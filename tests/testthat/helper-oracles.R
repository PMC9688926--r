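# Independent brute-force oracles used to cross-check the package's
# implementations on tiny inputs. These deliberately re-derive results in
# plain R from first principles.

# Priority-flood watershed oracle: Meyer flooding with watershed lines,
# written as explicit frontier scans (no heap, no C). Shares the package's
# documented determinism contract: flooding order (value, insertion order),
# neighbour order up/down/left/right then the four diagonals, seeding in
# column-major pixel order, pixels queued at most once.
flood_oracle <- function(im, markers, connectivity = 4) {
  nr <- nrow(im); nc <- ncol(im); n <- nr * nc
  di <- c(-1, 1, 0, 0, -1, -1, 1, 1)
  dj <- c(0, 0, -1, 1, -1, 1, -1, 1)
  nn <- if (connectivity == 8) 8 else 4
  label <- integer(n); status <- integer(n) # 0 unvisited, 1 queued, 2 final
  label[markers > 0] <- markers[markers > 0]
  status[markers > 0] <- 2L

  f_pix <- integer(0); f_val <- numeric(0); f_ctr <- integer(0)
  ctr <- 0L
  push_neighbours <- function(p) {
    i <- (p - 1) %% nr; j <- (p - 1) %/% nr
    for (k in seq_len(nn)) {
      ii <- i + di[k]; jj <- j + dj[k]
      if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) next
      q <- ii + jj * nr + 1
      if (status[q] == 0L) {
        status[q] <<- 1L
        ctr <<- ctr + 1L
        f_pix <<- c(f_pix, q); f_val <<- c(f_val, im[q])
        f_ctr <<- c(f_ctr, ctr)
      }
    }
  }
  for (p in seq_len(n)) if (status[p] == 2L) push_neighbours(p)

  while (length(f_pix)) {
    best <- order(f_val, f_ctr)[1]
    p <- f_pix[best]
    f_pix <- f_pix[-best]; f_val <- f_val[-best]; f_ctr <- f_ctr[-best]
    i <- (p - 1) %% nr; j <- (p - 1) %/% nr
    labs <- integer(0)
    for (k in seq_len(nn)) {
      ii <- i + di[k]; jj <- j + dj[k]
      if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) next
      q <- ii + jj * nr + 1
      if (status[q] == 2L && label[q] > 0) labs <- c(labs, label[q])
    }
    labs <- unique(labs)
    status[p] <- 2L
    if (length(labs) == 1L) {
      label[p] <- labs
      push_neighbours(p)
    } else {
      label[p] <- 0L # watershed line (or unreachable)
    }
  }
  matrix(label, nr, nc)
}

# Exact two-sided Mann-Whitney p by full enumeration of the C(n+m, n)
# rank splits (tie-free data only), with R's two-sided doubling convention.
mw_enum_oracle <- function(a, b) {
  n <- length(a); m <- length(b)
  r <- rank(c(a, b))
  u_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  splits <- combn(n + m, n)
  us <- apply(splits, 2, function(idx) sum(idx) - n * (n + 1) / 2)
  p <- if (u_obs > n * m / 2) 2 * mean(us >= u_obs) else
    2 * mean(us <= u_obs)
  min(p, 1)
}

# digital disk mask of radius r (pixel centres within r of the centre)
digital_disk <- function(r, pad = 2) {
  sz <- 2 * (r + pad) + 1
  cc <- r + pad + 1
  d2 <- outer((seq_len(sz) - cc)^2, (seq_len(sz) - cc)^2, "+")
  m <- matrix(0L, sz, sz)
  m[d2 <= r^2] <- 1L
  m
}
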