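# Fixtures built in code: tiny hand-written lineage tables and a
# well-separated synthetic spot grid for segmentation benchmarks.

# Single founder imaged at 0/6/12 h, no divisions.
tiny_static_table <- function() {
  lineage_table(data.frame(
    nucleus_id = "a", time_h = c(0, 6, 12), x_px = 10, y_px = 10,
    lineage_id = "L1", layer = "outer", is_antheridium = FALSE,
    parent_id = NA_character_), interval = 6)
}

# Founder divides in the (0,6] window (anticlinal), daughter b divides in
# (6,12] (periclinal). Counts 1, 2, 3.
tiny_division_table <- function() {
  rec <- rbind(
    data.frame(nucleus_id = "a", time_h = 0, x_px = 10, y_px = 10,
               lineage_id = "L1", layer = "outer", is_antheridium = FALSE,
               parent_id = NA_character_),
    data.frame(nucleus_id = c("b", "c"), time_h = 6, x_px = c(8, 12),
               y_px = 10, lineage_id = "L1", layer = "outer",
               is_antheridium = FALSE, parent_id = "a"),
    data.frame(nucleus_id = c("b2", "b3"), time_h = 12, x_px = c(7, 9),
               y_px = c(10, 14), lineage_id = "L1",
               layer = c("outer", "inner"), is_antheridium = FALSE,
               parent_id = "b"),
    data.frame(nucleus_id = "c", time_h = 12, x_px = 12, y_px = 10,
               lineage_id = "L1", layer = "outer", is_antheridium = FALSE,
               parent_id = NA_character_))
  lineage_table(rec, interval = 6)
}

# n_side x n_side grid of nuclei with jitter, spacing >> 4 * spot_sigma.
spot_grid_table <- function(n_side = 6, spacing = 18, jitter = 3,
                            seed = 42) {
  set.seed(seed)
  n <- n_side^2
  gx <- rep(seq(12, by = spacing, length.out = n_side), n_side) +
    runif(n, -jitter, jitter)
  gy <- rep(seq(12, by = spacing, length.out = n_side), each = n_side) +
    runif(n, -jitter, jitter)
  lineage_table(data.frame(
    nucleus_id = sprintf("n%03d", seq_len(n)), time_h = 0, x_px = gx,
    y_px = gy, lineage_id = "L1", layer = "outer", is_antheridium = FALSE,
    parent_id = NA_character_), interval = 6)
}

# Distance from each true position to the nearest detection.
nearest_detection_dist <- function(detections, x, y) {
  vapply(seq_along(x), function(i) {
    min(sqrt((detections$x - x[i])^2 + (detections$y - y[i])^2))
  }, numeric(1))
}
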