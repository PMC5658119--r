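# Independent brute-force oracles. These deliberately avoid the package's
# modular-arithmetic and diff-array implementations: distances walk base by
# base, pileups loop read by read and base by base.

# single-base steps from a to b in increasing-coordinate direction
oracle_steps_cw <- function(L, a, b) {
  n <- 0L
  p <- a
  while (p != b) {
    p <- if (p == L) 1L else p + 1L
    n <- n + 1L
    if (n > L) stop("walk did not terminate")
  }
  n
}

# positions strictly between a and b walking clockwise
oracle_strict_between <- function(L, a, b) {
  out <- integer(0)
  p <- a
  repeat {
    p <- if (p == L) 1L else p + 1L
    if (p == b) break
    out <- c(out, p)
    if (length(out) > L) stop("walk did not terminate")
  }
  out
}

oracle_wrap <- function(L, p) {
  while (p < 1) p <- p + L
  while (p > L) p <- p - L
  p
}

# per-read, per-base enumerators for pileup tracks
oracle_five_prime <- function(records, map) {
  L <- map$length
  plus <- numeric(L); minus <- numeric(L)
  for (i in seq_len(nrow(records))) {
    if (records$strand[i] == "plus") {
      p <- oracle_wrap(L, records$start[i])
      plus[p] <- plus[p] + 1
    } else {
      p <- oracle_wrap(L, records$start[i] + records$read_length[i] - 1)
      minus[p] <- minus[p] + 1
    }
  }
  list(plus = plus, minus = minus)
}

oracle_cleavage <- function(records, map) {
  fp <- oracle_five_prime(records, map)
  L <- map$length
  plus <- numeric(L); minus <- numeric(L)
  for (p in seq_len(L)) {
    if (fp$plus[p] > 0) {
      q <- oracle_wrap(L, p - 1)
      plus[q] <- plus[q] + fp$plus[p]
    }
    if (fp$minus[p] > 0) {
      q <- oracle_wrap(L, p + 1)
      minus[q] <- minus[q] + fp$minus[p]
    }
  }
  list(plus = plus, minus = minus)
}

oracle_occupancy <- function(records, map, extsize) {
  L <- map$length
  circular <- map$topology == "circular"
  plus <- numeric(L); minus <- numeric(L)
  for (i in seq_len(nrow(records))) {
    if (records$strand[i] == "plus") {
      span <- records$start[i] + 0:(extsize - 1)
    } else {
      fp <- records$start[i] + records$read_length[i] - 1
      span <- (fp - extsize + 1):fp
    }
    for (p in span) {
      if (circular) {
        q <- oracle_wrap(L, p)
      } else {
        if (p < 1 || p > L) next
        q <- p
      }
      if (records$strand[i] == "plus") plus[q] <- plus[q] + 1
      else minus[q] <- minus[q] + 1
    }
  }
  list(plus = plus, minus = minus)
}

random_records <- function(map, n) {
  len <- sample(20:80, n, replace = TRUE)
  start <- if (map$topology == "linear") {
    # keep reads fully on a linear reference
    vapply(len, function(l) sample.int(map$length - l + 1, 1), integer(1))
  } else {
    sample.int(map$length, n, replace = TRUE)
  }
  aligned_records(map$name, start = start, read_length = len,
                  strand = sample(c("plus", "minus"), n, replace = TRUE))
}

random_map <- function() {
  seq_map("rand", sample(200:2000, 1),
          sample(c("circular", "linear"), 1))
}
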