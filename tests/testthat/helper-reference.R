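# Pure-R reference implementation of the network trial, used as an
# independent oracle for the compiled fast path. Deliberately written in
# the most literal style: explicit per-step loops over cells and kernel
# sums, no shared code with the package internals beyond parameter lists.

ref_alpha <- function(dt, lam) (dt / lam) * exp((lam - dt) / lam)

ref_line_out <- function(events, t, lam, cutoff = 10) {
  if (length(events) == 0) return(0)
  age <- t - events
  age <- age[age > 0 & age <= cutoff * lam]
  if (length(age) == 0) return(0)
  sum(ref_alpha(age, lam))
}

ref_step <- function(cell, p, I, dt, sub, noise_sd) {
  v <- cell$v; u <- cell$u
  h <- dt / sub
  for (s in seq_len(sub))
    v <- v + h * (p$k * (v - p$v_r) * (v - p$v_t) - u + I) / p$C
  u <- u + dt * p$a * (p$b * (v - p$v_r) - u)
  if (noise_sd > 0) v <- v + stats::rnorm(1, 0, noise_sd)
  if (v >= p$v_peak) {
    list(v = p$c, u = u + p$d, event = TRUE, v_rec = p$v_peak)
  } else {
    list(v = v, u = u, event = FALSE, v_rec = v)
  }
}

ref_trial <- function(net, stim, noise_sd = 0, n_steps = 300, dt = 1,
                      sub = 2, stim_on = 100, stim_off = 1000,
                      glu_in_cleft = TRUE) {
  tri <- net$architecture == "tripartite"
  np <- net$n_pre; nq <- net$n_post
  pn <- net$neuron; pa <- net$astrocyte
  pre <- replicate(np, list(v = pn$v_r, u = 0), simplify = FALSE)
  post <- replicate(nq, list(v = pn$v_r, u = 0), simplify = FALSE)
  astro <- replicate(if (tri) nq else 0,
                     list(v = pa$v_r, u = 0), simplify = FALSE)
  syn <- rep(list(numeric(0)), np); ip3 <- rep(list(numeric(0)), np)
  kli <- rep(list(numeric(0)), nq)
  glu <- rep(list(numeric(0)), if (tri) nq else 0)
  I_K <- numeric(np); S_J <- numeric(nq)
  lam <- net$lambda
  for (it in seq_len(n_steps) - 1L) {
    t <- it * dt
    on <- t >= stim_on && t < stim_off
    syn_out <- vapply(syn, ref_line_out, numeric(1), t = t, lam = lam$syn)
    I_K <- I_K + syn_out * dt
    ip3_sum <- if (tri)
      sum(vapply(ip3, ref_line_out, numeric(1), t = t, lam = lam$ip3)) else 0
    glu_out <- vapply(glu, ref_line_out, numeric(1), t = t, lam = lam$glu)
    for (i in seq_len(np)) {
      pre[[i]] <- ref_step(pre[[i]], pn, if (on) stim[i] else 0, dt, sub,
                           noise_sd)
      if (pre[[i]]$event) {
        syn[[i]] <- c(syn[[i]], t)
        if (tri) ip3[[i]] <- c(ip3[[i]], t)
      }
    }
    for (j in seq_len(nq)) {
      g <- if (tri) net$fixed_weight * glu_out[j] else 0
      gc <- if (glu_in_cleft) g else 0
      I <- sum(net$weights[, j] * (syn_out + gc)) + g
      post[[j]] <- ref_step(post[[j]], pn, I, dt, sub, noise_sd)
      if (post[[j]]$event) kli[[j]] <- c(kli[[j]], t)
      S_J[j] <- S_J[j] + max(post[[j]]$v_rec, 0) * dt
    }
    if (tri) for (j in seq_len(nq)) {
      I <- net$fixed_weight * (ip3_sum + ref_line_out(kli[[j]], t, lam$k))
      astro[[j]] <- ref_step(astro[[j]], pa, I, dt, sub, 0)
      if (astro[[j]]$event) glu[[j]] <- c(glu[[j]], t)
    }
  }
  list(I_K = I_K, S_J = S_J, pre_events = syn, post_events = kli,
       astro_events = glu)
}
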