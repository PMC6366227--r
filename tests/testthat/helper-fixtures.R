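# Shared fixture builders. Everything is generated in code under fixed seeds.

# Trials for one participant with known true parameters.
make_trials <- function(delta, sigma, seed = 1, n_faces = 24L,
                        sched_seed = seed) {
  simulate_trials(build_schedule(sched_seed, n_faces), delta, sigma,
                  seed = seed)
}

# Hand-built trial frame where every quantity is chosen explicitly.
manual_trials <- function(x_ini, condition, x_post = x_ini) {
  fb <- compute_feedback(x_ini, condition)
  data.frame(face_id = seq_along(x_ini), condition = condition,
             offset_nominal = condition_offset(condition),
             clipped = fb$clipped, x_ini = x_ini,
             x_group = fb$group_rating, x_post = x_post,
             stringsAsFactors = FALSE)
}

# Independent per-trial likelihood oracle: plain loop over trials, normal
# CDF differences with boundary absorption. Deliberately unvectorized and
# separate from the package's implementation path.
oracle_nll <- function(trials, delta, sigma) {
  keep <- trials$condition != "NO_FEEDBACK" & !is.na(trials$x_group)
  tr <- trials[keep, , drop = FALSE]
  total <- 0
  for (i in seq_len(nrow(tr))) {
    mu <- tr$x_ini[i] + delta * (tr$x_group[i] - tr$x_ini[i])
    x <- tr$x_post[i]
    up <- if (x == 8) 1 else pnorm((x + 0.5 - mu) / sigma)
    dn <- if (x == 1) 0 else pnorm((x - 0.5 - mu) / sigma)
    total <- total - log(max(up - dn, 1e-300))
  }
  total
}
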