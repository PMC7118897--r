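## Independent oracles used to freeze expected values.  These deliberately
## go through Biostrings string arithmetic / exhaustive search rather than
## the package's own code paths.

oracleRevcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

oracleComplement <- function(b) {
  as.character(Biostrings::complement(Biostrings::DNAString(b)))
}

## trinucleotide class by reverse-complementing the whole context string
oracleTrinucClass <- function(ref, alt, five, three) {
  if (ref %in% c("A", "G")) {
    ctx <- oracleRevcomp(paste0(five, ref, three))
    five <- substr(ctx, 1, 1)
    ref2 <- substr(ctx, 2, 2)
    three <- substr(ctx, 3, 3)
    alt <- oracleComplement(alt)
    ref <- ref2
  }
  paste0(five, "[", ref, ">", alt, "]", three)
}

## canonical repeat-unit class by exhaustive minimum over rotations of the
## primitive unit and of its Biostrings reverse complement
oracleCanonicalUnit <- function(u) {
  n <- nchar(u)
  prim <- u
  for (d in seq_len(n - 1)) {
    if (n %% d == 0 && strrep(substr(u, 1, d), n / d) == u) {
      prim <- substr(u, 1, d)
      break
    }
  }
  rots <- function(x) {
    m <- nchar(x)
    sapply(seq_len(m), function(s)
      paste0(substring(x, s, m), substring(x, 1, s - 1)))
  }
  min(c(rots(prim), rots(oracleRevcomp(prim))))
}

allUnits <- function(lens) {
  unlist(lapply(lens, function(n) {
    apply(expand.grid(rep(list(c("A", "C", "G", "T")), n)), 1, paste,
          collapse = "")
  }), use.names = FALSE)
}

## exhaustive non-negative least squares on the unit simplex, step `res`;
## relies on sum(e) = 1 at the optimum (test problems are built that way)
gridSearchSimplex <- function(P, m, res = 1e-3) {
  k <- ncol(P)
  if (k == 2) {
    e1 <- seq(0, 1, by = res)
    E <- rbind(e1, 1 - e1)
  } else if (k == 3) {
    g <- expand.grid(e1 = seq(0, 1, by = res), e2 = seq(0, 1, by = res))
    g <- g[g$e1 + g$e2 <= 1 + 1e-12, ]
    E <- rbind(g$e1, g$e2, pmax(1 - g$e1 - g$e2, 0))
  } else {
    stop("grid oracle supports k = 2 or 3")
  }
  G <- crossprod(P)          # k x k
  b <- as.numeric(crossprod(P, m))
  ## ||m - P e||^2 = m'm - 2 b'e + e' G e, vectorized over grid columns
  quad <- colSums((G %*% E) * E)
  obj <- sum(m^2) - 2 * as.numeric(b %*% E) + quad
  best <- which.min(obj)
  list(e = E[, best], sse = obj[best])
}

## shared tiny reference: long enough that every trinucleotide context
## occurs multiple times
testReference <- function(seed = 11L, length = 20000L) {
  makeReference(seed = seed, contigs = c("chrA", "chrB"), length = length)
}
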