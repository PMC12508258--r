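# Independent brute-force oracles used to cross-check the image primitives.
# These are deliberately naive (queue flood fill, exhaustive level scans,
# exhaustive assignment enumeration) and share no code with the package
# implementations.

# Flood-fill connected-component labelling, 8-connectivity.
oracle_label <- function(mask) {
  h <- nrow(mask)
  w <- ncol(mask)
  lab <- matrix(0L, h, w)
  nxt <- 0L
  for (j in seq_len(w)) {
    for (i in seq_len(h)) {
      if (!mask[i, j] || lab[i, j] != 0L) next
      nxt <- nxt + 1L
      queue <- list(c(i, j))
      lab[i, j] <- nxt
      while (length(queue) > 0) {
        p <- queue[[1]]
        queue <- queue[-1]
        for (di in -1:1) {
          for (dj in -1:1) {
            ni <- p[1] + di
            nj <- p[2] + dj
            if (ni < 1 || ni > h || nj < 1 || nj > w) next
            if (mask[ni, nj] && lab[ni, nj] == 0L) {
              lab[ni, nj] <- nxt
              queue <- c(queue, list(c(ni, nj)))
            }
          }
        }
      }
    }
  }
  lab
}

# Brute-force particle detection: binarise > threshold, label, size-filter.
# (No hole filling / watershed: compare with those features disabled.)
oracle_detect <- function(image, threshold, min_size) {
  lab <- oracle_label(image > threshold)
  if (max(lab) == 0) {
    return(list())
  }
  comps <- split(which(lab > 0), lab[lab > 0])
  comps[lengths(comps) >= min_size]
}

# Brute-force maxima counting by exhaustive level scan: for each strict
# local maximum (plateaus handled as single summits via labelling), the
# prominence is its value minus the highest level at which its super-level
# component touches a strictly higher pixel; the global maximum's
# prominence is the image relief.
oracle_count_maxima <- function(image, tol) {
  h <- nrow(image)
  w <- ncol(image)
  if (max(image) == min(image)) {
    return(0L)
  }
  # summits: connected plateaus with no strictly higher 8-neighbour
  plat <- oracle_label(matrix(TRUE, h, w) &
    vapply(seq_len(h * w), function(p) {
      i <- (p - 1) %% h + 1
      j <- (p - 1) %/% h + 1
      v <- image[i, j]
      ok <- TRUE
      for (di in -1:1) {
        for (dj in -1:1) {
          ni <- i + di
          nj <- j + dj
          if (ni < 1 || ni > h || nj < 1 || nj > w) next
          if (image[ni, nj] > v) ok <- FALSE
        }
      }
      ok
    }, logical(1)) |> matrix(h, w))
  # restrict plateau labels to equal-valued summit plateaus
  count <- 0L
  gmax <- max(image)
  levels <- sort(unique(as.numeric(image)), decreasing = TRUE)
  for (k in seq_len(max(plat))) {
    cells <- which(plat == k)
    v <- image[cells[1]]
    if (length(unique(image[cells])) > 1) next # mixed plateau: not a summit
    if (v == gmax) {
      if (gmax - min(image) > tol) count <- count + 1L
      next
    }
    # descend levels until the component containing this summit holds a
    # strictly higher pixel
    prom <- NA_real_
    for (L in levels[levels <= v]) {
      comp <- oracle_label(image >= L)
      id <- comp[cells[1]]
      if (any(image[comp == id] > v)) {
        prom <- v - L
        break
      }
    }
    if (!is.na(prom) && prom > tol) count <- count + 1L
  }
  count
}

# Exhaustive maximal matching: among all one-to-one assignments within the
# radius, pick the one with the most pairs, then the smallest total
# distance. Feasible for <= 6 particles per side.
oracle_match <- function(ax, ay, bx, by, radius) {
  na <- length(ax)
  nb <- length(bx)
  d <- sqrt(outer(ax, bx, "-")^2 + outer(ay, by, "-")^2)
  best <- list(n = -1L, total = Inf, pairs = NULL)
  recurse <- function(i, used_b, pairs, total) {
    if (i > na) {
      n <- nrow(pairs)
      if (n > best$n || (n == best$n && total < best$total - 1e-12)) {
        best <<- list(n = n, total = total, pairs = pairs)
      }
      return(invisible())
    }
    recurse(i + 1L, used_b, pairs, total) # leave a_i unmatched
    for (j in seq_len(nb)) {
      if (!used_b[j] && d[i, j] <= radius) {
        used_b[j] <- TRUE
        recurse(
          i + 1L, used_b,
          rbind(pairs, data.frame(a = i, b = j)), total + d[i, j]
        )
        used_b[j] <- FALSE
      }
    }
  }
  recurse(1L, logical(nb), data.frame(a = integer(), b = integer()), 0)
  best
}

# Minimal particle tibble for matcher tests.
toy_particles <- function(x, y, intensity = NULL) {
  tibble::tibble(
    id = seq_along(x), x = x, y = y,
    integrated = intensity %||% rep(100, length(x))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
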