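# Independent reference implementations used as oracles.  These follow
# the documented conventions (scoring, tie-breaks) but are coded
# separately from the package internals.

# ---- reference DP for glocal (end-gap-free) affine alignment ----------
oracle_glocal <- function(a, b, go = 11, ge = 1) {
  e <- new.env(); data("BLOSUM62", package = "Biostrings", envir = e)
  alpha <- c("A","R","N","D","C","Q","E","G","H","I",
             "L","K","M","F","P","S","T","W","Y","V","X")
  S <- e$BLOSUM62[alpha, alpha]
  ai <- match(strsplit(a, "")[[1]], alpha); ai[is.na(ai)] <- 21L
  bi <- match(strsplit(b, "")[[1]], alpha); bi[is.na(bi)] <- 21L
  n <- length(ai); m <- length(bi); NEG <- -1e18
  M <- X <- Y <- matrix(NEG, n + 1, m + 1)
  for (i in 1:n) for (j in 1:m) {
    prev <- if (i == 1 || j == 1) 0 else max(M[i, j], X[i, j], Y[i, j])
    M[i + 1, j + 1] <- S[ai[i], bi[j]] + prev
    if (i >= 2) X[i + 1, j + 1] <- max(M[i, j + 1] - go - ge,
                                       X[i, j + 1] - ge)
    if (j >= 2) Y[i + 1, j + 1] <- max(M[i + 1, j] - go - ge,
                                       Y[i + 1, j] - ge)
  }
  best <- NEG; ti <- tj <- -1L
  for (j in 0:m) {
    h <- if (j == 0) 0 else max(M[n + 1, j + 1], X[n + 1, j + 1],
                                Y[n + 1, j + 1])
    if (h > best) { best <- h; ti <- n; tj <- j }
  }
  for (i in 0:(n - 1)) {
    h <- if (i == 0) 0 else max(M[i + 1, m + 1], X[i + 1, m + 1],
                                Y[i + 1, m + 1])
    if (h > best) { best <- h; ti <- i; tj <- m }
  }
  matches <- 0L; columns <- 0L
  if (ti > 0 && tj > 0) {
    i <- ti; j <- tj
    vals <- c(M[i + 1, j + 1], X[i + 1, j + 1], Y[i + 1, j + 1])
    state <- which.max(vals)  # ties -> lowest index = M > X > Y
    repeat {
      if (state == 1) {
        columns <- columns + 1L
        if (ai[i] == bi[j]) matches <- matches + 1L
        if (i == 1 || j == 1) break
        vals <- c(M[i, j], X[i, j], Y[i, j])
        state <- which.max(vals)
        i <- i - 1L; j <- j - 1L
      } else if (state == 2) {
        columns <- columns + 1L
        fromM <- M[i, j + 1] - go - ge
        state <- if (abs(fromM - X[i + 1, j + 1]) < 1e-9) 1L else 2L
        i <- i - 1L
      } else {
        columns <- columns + 1L
        fromM <- M[i + 1, j] - go - ge
        state <- if (abs(fromM - Y[i + 1, j + 1]) < 1e-9) 1L else 3L
        j <- j - 1L
      }
    }
  }
  list(score = best, matches = matches, columns = columns,
       identity = if (columns > 0) matches / columns else 0)
}

random_protein <- function(n) {
  paste(sample(c("A","R","N","D","C","Q","E","G","H","I",
                 "L","K","M","F","P","S","T","W","Y","V"),
               n, replace = TRUE), collapse = "")
}

random_dna_str <- function(n) {
  paste(sample(c("A","C","G","T"), n, replace = TRUE), collapse = "")
}

# ---- brute-force ORF enumeration (spec semantics, string-based) -------
oracle_orfs <- function(seq) {
  gc <- Biostrings::GENETIC_CODE
  out <- list()
  for (frame in 0:2) {
    n <- nchar(seq)
    if (frame + 3 > n) next
    starts <- seq(frame + 1, n - 2, by = 3)
    cods <- substring(seq, starts, starts + 2)
    pep <- gc[cods]; pep[is.na(pep)] <- "X"
    pep <- paste(pep, collapse = "")
    stop_pos <- which(strsplit(pep, "")[[1]] == "*")
    seg_start <- c(1L, stop_pos + 1L)
    seg_end <- c(stop_pos - 1L, nchar(pep))
    for (k in seq_along(seg_start)) {
      lo <- seg_start[k]; hi <- seg_end[k]
      if (hi < lo) next
      seg <- substr(pep, lo, hi)
      has_stop <- k <= length(stop_pos)
      first <- substr(seg, 1, 1)
      if (lo == 1 && first != "M")
        out[[length(out) + 1]] <- list(frame = frame, start = frame + 3 * (lo - 1),
                                       end = frame + 3 * hi, protein = seg,
                                       has_start = FALSE, has_stop = has_stop)
      mpos <- regexpr("M", seg, fixed = TRUE)
      if (mpos > 0) {
        a <- lo + mpos - 1
        out[[length(out) + 1]] <- list(frame = frame, start = frame + 3 * (a - 1),
                                       end = frame + 3 * hi,
                                       protein = substr(seg, mpos, nchar(seg)),
                                       has_start = TRUE, has_stop = has_stop)
      }
    }
  }
  df <- do.call(rbind, lapply(out, as.data.frame))
  if (is.null(df)) return(df)
  df[order(df$frame, df$start), ]
}

# ---- naive O(n^3) Ward (D2) agglomeration -----------------------------
oracle_ward_merges <- function(X) {
  n <- nrow(X)
  D <- as.matrix(dist(X))
  clusters <- as.list(seq_len(n))
  sizes <- rep(1, n)
  active <- rep(TRUE, n)
  merges <- list(); heights <- numeric(0)
  Dw <- D
  while (sum(active) > 1) {
    idx <- which(active)
    best <- c(NA, NA); bh <- Inf
    for (x in idx) for (y in idx) if (x < y && Dw[x, y] < bh) {
      bh <- Dw[x, y]; best <- c(x, y)
    }
    i <- best[1]; j <- best[2]
    merges[[length(merges) + 1]] <- sort(unlist(clusters[c(i, j)]))
    heights <- c(heights, bh)
    # Lance-Williams update for Ward.D2 (on Euclidean distances)
    for (k in idx) {
      if (k == i || k == j) next
      Dw[i, k] <- Dw[k, i] <- sqrt(
        ((sizes[i] + sizes[k]) * Dw[i, k]^2 +
         (sizes[j] + sizes[k]) * Dw[j, k]^2 -
         sizes[k] * Dw[i, j]^2) / (sizes[i] + sizes[j] + sizes[k]))
    }
    clusters[[i]] <- c(clusters[[i]], clusters[[j]])
    sizes[i] <- sizes[i] + sizes[j]
    active[j] <- FALSE
  }
  list(merges = merges, heights = heights)
}

# ---- dense grid scan for the isoelectric point ------------------------
oracle_pi_grid <- function(protein, step = 1e-4) {
  pk_side <- c(D = 4.05, E = 4.45, C = 9.0, Y = 10.0,
               H = 5.98, K = 10.0, R = 12.0)
  pk_nterm <- c(A = 7.59, M = 7.00, S = 6.93, P = 8.36, T = 6.82,
                V = 7.44, E = 7.70, G = 7.50)
  s <- strsplit(protein, "")[[1]]
  nt <- if (s[1] %in% names(pk_nterm)) pk_nterm[[s[1]]] else 7.5
  pH <- seq(0, 14, by = step)
  ch <- 1 / (1 + 10^(pH - nt)) - 1 / (1 + 10^(3.55 - pH))
  for (a in c("H", "K", "R"))
    ch <- ch + sum(s == a) / (1 + 10^(pH - pk_side[[a]]))
  for (a in c("D", "E", "C", "Y"))
    ch <- ch - sum(s == a) / (1 + 10^(pk_side[[a]] - pH))
  pH[which.min(abs(ch))]
}
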