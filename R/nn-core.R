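# Shared numeric core for the neural encoders: initialization, Adam, and
# elementwise nonlinearities. Parameters live in (possibly nested) named lists
# of base matrices/vectors; the optimizer walks the same structure.

relu <- function(x) if (is.matrix(x)) relu_cpp(x) else pmax(x, 0)

sigmoid_ <- function(x) 1 / (1 + exp(-x))

glorot <- function(nr, nc) {
  s <- sqrt(6 / (nr + nc))
  matrix(runif(nr * nc, -s, s), nr, nc)
}

zeros <- function(n) numeric(n)

# elementwise walk over two parallel nested lists
map_params2 <- function(a, b, f) {
  if (is.list(a)) {
    out <- Map(function(x, y) map_params2(x, y, f), a, b)
    return(out)
  }
  f(a, b)
}

map_params3 <- function(a, b, c, f) {
  if (is.list(a)) {
    return(Map(function(x, y, z) map_params3(x, y, z, f), a, b, c))
  }
  f(a, b, c)
}

zero_like <- function(p) {
  if (is.list(p)) return(lapply(p, zero_like))
  p * 0
}

adam_init <- function(params) {
  list(m = zero_like(params), v = zero_like(params), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- map_params2(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- map_params2(state$v, grads, function(v, g) beta2 * v + (1 - beta2) * g^2)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  params <- map_params3(params, state$m, state$v, function(p, m, v) {
    p - lr * (m / bc1) / (sqrt(v / bc2) + eps)
  })
  list(params = params, state = state)
}

# numerically safe binary cross-entropy on logits; returns loss and dlogits
bce_with_logits <- function(logits, y) {
  p <- sigmoid_(logits)
  eps <- 1e-12
  loss <- -mean(y * log(p + eps) + (1 - y) * log(1 - p + eps))
  list(loss = loss, dlogits = (p - y) / length(y), prob = p)
}
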