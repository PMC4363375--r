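# Internal helpers shared across modules.

# Evaluate expr with a locally set RNG seed, restoring the caller's RNG
# state afterwards so library functions never clobber user randomness.
withSeed <- function(seed, expr) {
  if (!is.null(seed) && !is.na(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Kahn's algorithm on the child->parent relation. Returns NULL when the
# relation is acyclic, otherwise one cycle as a vector of ids.
.findCycle <- function(d) {
  ids <- d$id
  parents <- cbind(match(d$father, ids), match(d$mother, ids))
  n <- length(ids)
  indeg <- integer(n)            # number of unresolved parents per individual
  children <- vector("list", n)  # parent index -> child indices
  for (i in seq_len(n)) {
    ps <- parents[i, ]
    ps <- ps[!is.na(ps)]
    indeg[i] <- length(ps)
    for (p in ps) children[[p]] <- c(children[[p]], i)
  }
  queue <- which(indeg == 0L)
  done <- 0L
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]; done <- done + 1L
    for (ch in children[[v]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (done == n) return(NULL)
  # walk parent links from any unresolved node until a repeat closes the cycle
  start <- which(indeg > 0L)[1L]
  seen <- integer(0)
  v <- start
  while (!(v %in% seen)) {
    seen <- c(seen, v)
    ps <- parents[v, ]; ps <- ps[!is.na(ps) & indeg[ps] > 0L]
    v <- ps[1L]
  }
  cyc <- seen[which(seen == v):length(seen)]
  ids[c(cyc, v)]
}

# Indices in ancestor-before-descendant order (founders first, ties by
# input order via generation depth then position).
.topoOrder <- function(d) {
  depth <- .generationDepth(d)
  order(depth, seq_len(nrow(d)))
}

# Generation depth: founders 0, otherwise 1 + max(parent depths).
.generationDepth <- function(d) {
  ids <- d$id
  fi <- match(d$father, ids)
  mi <- match(d$mother, ids)
  n <- length(ids)
  depth <- rep(NA_integer_, n)
  depth[is.na(fi)] <- 0L
  repeat {
    todo <- which(is.na(depth))
    if (!length(todo)) break
    progressed <- FALSE
    for (i in todo) {
      df <- depth[fi[i]]; dm <- depth[mi[i]]
      if (!is.na(df) && !is.na(dm)) {
        depth[i] <- max(df, dm) + 1L
        progressed <- TRUE
      }
    }
    if (!progressed) stop("cannot assign generation depth (cyclic pedigree?)")
  }
  depth
}

.variantKey <- function(records) {
  paste(records$chrom, records$pos, records$ref, records$alt, sep = ":")
}

.assertCount <- function(x, name, min = 0) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x))
    stop(sprintf("'%s' must be a single integer >= %d", name, min))
  as.integer(x)
}

.assertProb <- function(x, name, open = FALSE) {
  lo <- if (open) 0 else -1e-15
  hi <- if (open) 1 else 1 + 1e-15
  ok <- is.numeric(x) & !is.na(x) & (if (open) x > 0 & x < 1 else x >= 0 & x <= 1)
  if (!all(ok))
    stop(sprintf("'%s' must be %s", name,
                 if (open) "strictly between 0 and 1" else "a probability in [0, 1]"))
  as.numeric(x)
}
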