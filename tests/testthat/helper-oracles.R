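# Independent brute-force oracles. These deliberately share no code with the
# package implementations: index-by-index loops, naive O(n^3) linkage, naive
# region enumeration.

# map an out-of-range index onto 1..n by symmetric reflection (edge repeated)
reflect_idx <- function(i, n) {
  while (i < 1L || i > n) {
    if (i < 1L) i <- 1L - i
    if (i > n) i <- 2L * n + 1L - i
  }
  i
}

oracle_local_mean_mask <- function(img, radius, offset) {
  n <- nrow(img); p <- ncol(img)
  out <- matrix(FALSE, n, p)
  for (i in seq_len(n)) for (j in seq_len(p)) {
    acc <- 0
    for (di in -radius:radius) for (dj in -radius:radius) {
      acc <- acc + img[reflect_idx(i + di, n), reflect_idx(j + dj, p)]
    }
    out[i, j] <- img[i, j] > acc / (2 * radius + 1)^2 + offset
  }
  out
}

oracle_median_smooth <- function(img, radius) {
  n <- nrow(img); p <- ncol(img)
  if (radius < 0.5) return(img)
  rmax <- as.integer(ceiling(radius + 1))
  out <- matrix(0, n, p)
  for (i in seq_len(n)) for (j in seq_len(p)) {
    vals <- c()
    for (di in -rmax:rmax) for (dj in -rmax:rmax) {
      if (di^2 + dj^2 <= radius^2 + 1)
        vals <- c(vals, img[reflect_idx(i + di, n), reflect_idx(j + dj, p)])
    }
    out[i, j] <- median(vals)
  }
  out
}

# naive agglomerative clustering; returns sorted merge heights
oracle_linkage_heights <- function(mat, method = c("complete", "average")) {
  method <- match.arg(method)
  d <- as.matrix(dist(mat))
  clusters <- as.list(seq_len(nrow(mat)))
  heights <- numeric(0)
  cluster_dist <- function(a, b) {
    pair <- outer(a, b, Vectorize(function(i, j) d[i, j]))
    if (method == "complete") max(pair) else mean(pair)
  }
  while (length(clusters) > 1L) {
    best <- c(NA, NA); bestd <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      dd <- cluster_dist(clusters[[i]], clusters[[j]])
      if (dd < bestd) { bestd <- dd; best <- c(i, j) }
    }
    heights <- c(heights, bestd)
    clusters[[best[1L]]] <- c(clusters[[best[1L]]], clusters[[best[2L]]])
    clusters[[best[2L]]] <- NULL
  }
  sort(heights)
}

oracle_welch_p <- function(x, y) {
  sx <- var(x) / length(x); sy <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(sx + sy)
  df <- (sx + sy)^2 / (sx^2 / (length(x) - 1) + sy^2 / (length(y) - 1))
  2 * pt(-abs(t), df)
}

oracle_paired_p <- function(x, y) {
  d <- x - y
  t <- mean(d) / (sd(d) / sqrt(length(d)))
  2 * pt(-abs(t), length(d) - 1)
}

oracle_pearson <- function(x, y) {
  n <- length(x)
  num <- sum((x - mean(x)) * (y - mean(y)))
  num / sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# naive HRD-LOH scorer: explicit scan, no vectorised shortcuts
oracle_hrd_score <- function(segments, model, min_length = 1e7) {
  segments <- segments[order(segments$chrom, segments$start), ]
  segments <- segments[!(segments$chrom %in% c("X", "Y", "chrX", "chrY")), ]
  score <- 0L
  for (ch in unique(segments$chrom)) {
    s <- segments[segments$chrom == ch, ]
    lo <- min(s$start); hi <- max(s$end)
    i <- 1L
    while (i <= nrow(s)) {
      is_loh <- min(s$cn_a[i], s$cn_b[i]) < model$loh_allele_threshold
      if (!is_loh) { i <- i + 1L; next }
      j <- i
      while (j < nrow(s) &&
             min(s$cn_a[j + 1L], s$cn_b[j + 1L]) < model$loh_allele_threshold &&
             s$start[j + 1L] == s$end[j]) j <- j + 1L
      rstart <- s$start[i]; rend <- s$end[j]
      tot_len <- 0; tot_tcn <- 0
      for (q in i:j) {
        tot_len <- tot_len + (s$end[q] - s$start[q])
        tot_tcn <- tot_tcn + s$tcn[q] * (s$end[q] - s$start[q])
      }
      mean_tcn <- tot_tcn / tot_len
      if ((rend - rstart) > min_length &&
          mean_tcn < model$loss_threshold &&
          !(rstart == lo && rend == hi)) score <- score + 1L
      i <- j + 1L
    }
  }
  score
}

# random segment table mixing background, loss/copy-neutral/whole-chrom LOH
random_segment_table <- function(seed, ploidy_class = "2n") {
  set.seed(seed)
  chroms <- as.character(1:4)
  sizes <- setNames(round(runif(4, 6e7, 1.5e8)), chroms)
  base_tcn <- if (ploidy_class == "2n") 2 else 4
  loss_tcn <- if (ploidy_class == "2n") 1 else 2
  rows <- list()
  for (ch in chroms) {
    kind <- sample(c("none", "loss", "neutral", "whole", "short", "multi"), 1L)
    size <- sizes[[ch]]
    add <- function(st, en, tcn, a, b)
      rows[[length(rows) + 1L]] <<- data.frame(chrom = ch, start = st, end = en,
                                               tcn = tcn, cn_a = a, cn_b = b)
    if (kind == "whole") {
      add(0, size, loss_tcn, loss_tcn, 0)
    } else if (kind == "none") {
      add(0, size, base_tcn, base_tcn / 2, base_tcn / 2)
    } else {
      len <- switch(kind, loss = runif(1, 1.1e7, 3e7),
                    neutral = runif(1, 1.1e7, 3e7),
                    short = runif(1, 2e6, 9.9e6),
                    multi = runif(1, 0.6e7, 2e7))
      st <- runif(1, 0, size - len - 2e7)
      tcn <- if (kind == "neutral") base_tcn else loss_tcn
      add(0, st, base_tcn, base_tcn / 2, base_tcn / 2)
      add(st, st + len, tcn, tcn, 0)
      if (kind == "multi") {
        # a book-ended second LOH piece, sometimes changing the region class
        len2 <- runif(1, 0.6e7, 2e7)
        tcn2 <- sample(c(loss_tcn, base_tcn), 1L)
        add(st + len, st + len + len2, tcn2, tcn2, 0)
        add(st + len + len2, size, base_tcn, base_tcn / 2, base_tcn / 2)
      } else {
        add(st + len, size, base_tcn, base_tcn / 2, base_tcn / 2)
      }
    }
  }
  do.call(rbind, rows)
}

adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  expected <- sum_a * sum_b / n
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# turn a simulated dose-response series into an area table for
# assemble_metrics: fixed 0-h total area, growth/ratio converted to areas
series_to_area_table <- function(series, plate = "p1", cell_line = "L1",
                                 culture = "3D", drug = "drugA",
                                 timepoint = 72, total0 = 10000) {
  rows <- lapply(seq_len(nrow(series)), function(i) {
    s <- series[i, ]
    well <- if (s$role == "treated")
      sprintf("B%02d", match(s$dose, sort(unique(series$dose)))) else "C01"
    tot_t <- round(total0 * s$growth)
    pi_t <- round(tot_t * s$death_ratio)
    rbind(
      data.frame(plate = plate, well = well,
                 position = paste0("p", s$position), cell_line = cell_line,
                 culture = culture, drug = ifelse(s$role == "treated", drug, ""),
                 concentration = s$dose, unit = "uM", role = s$role,
                 timepoint_h = 0, area_pi = round(0.05 * total0),
                 area_total = total0, qc_flags = "",
                 stringsAsFactors = FALSE),
      data.frame(plate = plate, well = well,
                 position = paste0("p", s$position), cell_line = cell_line,
                 culture = culture, drug = ifelse(s$role == "treated", drug, ""),
                 concentration = s$dose, unit = "uM", role = s$role,
                 timepoint_h = timepoint, area_pi = pi_t, area_total = tot_t,
                 qc_flags = "", stringsAsFactors = FALSE))
  })
  do.call(rbind, rows)
}
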