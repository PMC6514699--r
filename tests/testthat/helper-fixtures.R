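# Shared fixtures: scenes are rendered at reduced resolution (800 px wide)
# for speed and cached per test file so repeated tests reuse them.

.scene_cache <- new.env(parent = emptyenv())

test_scene <- function(..., with_mask = FALSE) {
  args <- utils::modifyList(list(image_width_px = 800), list(...))
  key <- paste(deparse(args), collapse = "") |> paste0(":", with_mask)
  if (is.null(.scene_cache[[key]])) {
    spec <- do.call(scene_spec, args)
    .scene_cache[[key]] <- list(spec = spec,
                                scene = render_scene(spec, with_mask = with_mask))
  }
  .scene_cache[[key]]
}

measure_scene <- function(ts) {
  measure(ts$scene$image, config_for_scene(ts$spec))
}

rel_err_pct <- function(measured, true) 100 * (measured - true) / true

# Brute-force Otsu oracle: try every threshold, compute the between-class
# variance from the raw values directly.
otsu_bruteforce <- function(v) {
  v <- as.integer(round(as.numeric(v)))
  best_t <- -1L
  best_s <- -Inf
  for (t in 0:254) {
    lo <- v[v <= t]
    hi <- v[v > t]
    if (!length(lo) || !length(hi)) next
    w0 <- length(lo) / length(v)
    s <- w0 * (1 - w0) * (mean(lo) - mean(hi))^2
    if (s > best_s + 1e-12) { best_s <- s; best_t <- t }
  }
  best_t
}

# Flood-fill oracle for interior pixel counts: fill the background from the
# matrix border (4-connected); everything not reached and not foreground is
# an enclosed hole, so interior = foreground + holes.
interior_bruteforce <- function(comp) {
  w <- nrow(comp); h <- ncol(comp)
  visited <- matrix(FALSE, w, h)
  queue <- matrix(0L, 2L * (w + h) + 8L, 2)
  qn <- 0L
  push <- function(x, y) {
    if (x < 1L || x > w || y < 1L || y > h) return()
    if (visited[x, y] || comp[x, y]) return()
    qn <<- qn + 1L
    if (qn > nrow(queue)) queue <<- rbind(queue, queue)
    queue[qn, ] <<- c(x, y)
    visited[x, y] <<- TRUE
  }
  for (x in 1:w) { push(x, 1L); push(x, h) }
  for (y in 1:h) { push(1L, y); push(w, y) }
  while (qn > 0L) {
    p <- queue[qn, ]; qn <- qn - 1L
    push(p[1] - 1L, p[2]); push(p[1] + 1L, p[2])
    push(p[1], p[2] - 1L); push(p[1], p[2] + 1L)
  }
  sum(comp) + sum(!visited & !comp)
}

# Random 4-connected blob mask for oracle tests.
random_blob <- function(w, h, steps = 200) {
  m <- matrix(FALSE, w, h)
  x <- w %/% 2; y <- h %/% 2
  m[x, y] <- TRUE
  for (i in seq_len(steps)) {
    d <- sample(4, 1)
    x <- min(max(x + c(1, -1, 0, 0)[d], 2), w - 1)
    y <- min(max(y + c(0, 0, 1, -1)[d], 2), h - 1)
    m[x, y] <- TRUE
  }
  m
}

# Hand-built plate mask (no camera): frame ring with tick marks on the upper
# and left borders, plus an optional solid blob.  Geometry in pixels.
toy_plate_mask <- function(w = 520, h = 420, thick = 20, pitch = 10,
                           tick_len = 30, tick_w = 3, blob = TRUE,
                           broken_ticks = FALSE) {
  m <- matrix(0L, w, h)
  m[1:w, 1:thick] <- 1L; m[1:w, (h - thick + 1):h] <- 1L
  m[1:thick, 1:h] <- 1L; m[(w - thick + 1):w, 1:h] <- 1L
  half <- tick_w %/% 2
  if (tick_len > 0) {
    for (cx in seq(thick + pitch, w - thick - pitch, by = pitch)) {
      m[(cx - half):(cx + half) + 1, thick + (1:tick_len)] <- 1L
    }
    for (cy in seq(thick + pitch, h - thick - pitch, by = pitch)) {
      m[thick + (1:tick_len), (cy - half):(cy + half) + 1] <- 1L
    }
  }
  if (broken_ticks) {
    # split every tick with a one-pixel gap halfway along its stroke
    mid <- thick + tick_len %/% 2
    m[(thick + 1):(w - thick), mid] <- 0L   # cuts the top-border ticks
    m[mid, (thick + 1):(h - thick)] <- 0L   # cuts the left-border ticks
  }
  if (blob) m[(w %/% 2 - 40):(w %/% 2 + 40), (h %/% 2 - 30):(h %/% 2 + 30)] <- 1L
  binary_mask(m)
}

# Unclassed numeric matrix view (mirror of the package-internal helper).
as_matrix_test <- function(x) {
  x <- unclass(x)
  storage.mode(x) <- "double"
  x
}
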