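# Shared builders for synthetic inputs. Everything is generated in code; no
# binary fixtures.

one_cell_scene <- function(..., seed = 1L) {
  scene_params(
    width = 32, height = 32,
    cells = list(scene_cell(
      soma = c(15, 15, 8, 6), nucleus = c(15, 15, 3, 2), cell_id = "c1"
    )),
    seed = seed,
    ...
  )
}

constant_ratio_traces <- function(ratio, n_frames, cell_id = "c1",
                                  dt_min = 0.25) {
  tibble::tibble(
    cell_id = cell_id,
    time_min = (seq_len(n_frames) - 1) * dt_min,
    ratio = ratio
  )
}

# a plain ratio trace tibble on a regular grid
make_trace <- function(R, dt_min = 0.25, cell_id = "c1") {
  tibble::tibble(
    cell_id = cell_id,
    time_min = (seq_along(R) - 1) * dt_min,
    R = R
  )
}

make_rel_trace <- function(value, dt_min = 0.25, cell_id = "c1") {
  tibble::tibble(
    cell_id = cell_id,
    time_min = (seq_along(value) - 1) * dt_min,
    value = value
  )
}

# brute-force two-sided point-probability Fisher p via dhyper (independent of
# the lchoose-based implementation path)
fisher_brute <- function(tab) {
  r1 <- sum(tab[1, ])
  c1 <- sum(tab[, 1])
  n <- sum(tab)
  support <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- stats::dhyper(support, c1, n - c1, r1)
  p_obs <- probs[support == tab[1, 1]]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
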