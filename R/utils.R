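# internal geometry and validation helpers

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# unit vector in the xy-plane at `deg` degrees from +x, counter-clockwise
unit2 <- function(deg) {
  a <- deg2rad(deg)
  c(cos(a), sin(a))
}

# 3x3 rotation matrix about an arbitrary unit axis (Rodrigues)
rotation_matrix <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  th <- deg2rad(angle_deg)
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

stop_param <- function(...) {
  stop(structure(
    class = c("hexfract_parameter_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

stop_geometry <- function(...) {
  stop(structure(
    class = c("hexfract_geometry_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

stop_size_limit <- function(...) {
  stop(structure(
    class = c("hexfract_size_limit_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

check_scalar_number <- function(x, name, positive = FALSE, integerish = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_param(name, " must be a single finite number")
  }
  if (positive && x <= 0) stop_param(name, " must be > 0")
  if (integerish && abs(x - round(x)) > 1e-8) stop_param(name, " must be an integer")
  invisible(x)
}
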