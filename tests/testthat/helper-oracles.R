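## Shared generators and independent oracles for the test suite.

## random parameter draw over clinically plausible ranges
rand_params <- function() {
  ward_params(r = runif(1, 0.5, 8), K = runif(1, 10, 300),
              a = runif(1, 0.5, 6), b1 = runif(1, 0.5, 3),
              b2 = runif(1, 0.5, 3), beta = runif(1, 0.5, 8),
              zeta = runif(1, 0, 3), epsilon = sample(c(0, 1), 1),
              gamma1 = runif(1, 1, 6), gamma2 = runif(1, 1, 6),
              m1 = runif(1, 0.3, 3), m2 = runif(1, 0.3, 3),
              m3 = runif(1, 0.3, 3), omega = runif(1, 0, 5))
}

## random admissible state (strictly positive, spanning several decades)
rand_state <- function(scale = 100) {
  c(E = 10^runif(1, -2, log10(2 * scale)),
    C = 10^runif(1, -2, log10(2 * scale)),
    G = runif(1, 0, 2 * scale),
    I = runif(1, 0, 5 * scale))
}

## random 4x4 matrix with the model's structural zero pattern
rand_patterned_matrix <- function(sd = 2) {
  J <- matrix(rnorm(16, sd = sd), 4, 4)
  J[1, 3] <- J[1, 4] <- J[3, 1] <- J[4, 3] <- 0
  J
}

## independent characteristic-polynomial oracle: evaluate det(lambda*I - J)
## at five nodes and solve the Vandermonde system for the coefficients.
charpoly_oracle <- function(J) {
  nodes <- c(-2, -1, 0, 1, 2)
  vals <- vapply(nodes, function(l) det(l * diag(4) - J), numeric(1))
  V <- outer(nodes, 4:0, `^`)
  coef <- solve(V, vals)            # (1, A1, A2, A3, A4)
  coef[-1] / coef[1]
}

## the published coefficient formulas (valid under the model zero pattern)
charpoly_printed <- function(J) {
  a <- function(i, j) J[i, j]
  A1 <- -a(1,1) - a(2,2) - a(3,3) - a(4,4)
  A2 <- a(1,1)*a(2,2) + a(1,1)*a(3,3) + a(1,1)*a(4,4) - a(1,2)*a(2,1) +
    a(2,2)*a(3,3) + a(2,2)*a(4,4) - a(2,3)*a(3,2) - a(2,4)*a(4,2) +
    a(3,3)*a(4,4)
  A3 <- -a(1,1)*a(2,2)*a(3,3) - a(1,1)*a(2,2)*a(4,4) +
    a(1,1)*a(2,3)*a(3,2) + a(1,1)*a(2,4)*a(4,2) - a(1,1)*a(3,3)*a(4,4) +
    a(1,2)*a(2,1)*a(3,3) + a(1,2)*a(2,1)*a(4,4) - a(1,2)*a(2,4)*a(4,1) -
    a(2,2)*a(3,3)*a(4,4) + a(2,3)*a(3,2)*a(4,4) - a(2,3)*a(3,4)*a(4,2) +
    a(2,4)*a(3,3)*a(4,2)
  A4 <- a(1,1)*a(2,2)*a(3,3)*a(4,4) - a(1,1)*a(2,3)*a(3,2)*a(4,4) +
    a(1,1)*a(2,3)*a(3,4)*a(4,2) - a(1,1)*a(2,4)*a(3,3)*a(4,2) -
    a(1,2)*a(2,1)*a(3,3)*a(4,4) - a(1,2)*a(2,3)*a(3,4)*a(4,1) +
    a(1,2)*a(2,4)*a(3,3)*a(4,1)
  c(A1 = A1, A2 = A2, A3 = A3, A4 = A4)
}

## relative max-norm difference between two matrices/vectors
rel_err <- function(x, y) max(abs(x - y)) / (1 + max(abs(y)))
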