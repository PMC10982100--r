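// Training engine for low-dimensional neural ODEs.
//
// Fixed-step classical RK4 over a caller-supplied time grid
// (discretize-then-differentiate): the reverse pass backpropagates the
// pooled loss through every RK4 stage, so gradients are exact for the
// discretized trajectory.  State dimension is 1 or 2 and every network has
// one hidden layer, which keeps the whole computation cheap enough for
// full-batch Adam over thousands of epochs on one CPU.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// structure codes (keep in sync with R/node_model.R)
enum Structure {
  ST_BASIC = 0,     // dx = f(x, t),                     x(0) = d/V
  ST_SEPARATED = 1, // dx = fC1(x) + (d/V) fC2(t),       x(0) = d/V
  ST_ABSORPTION = 2,// xA' = d fA1(t) - fA2(xA)
                    // xC' = fA2(xA) - fC1(xC) - d fC2(t)
  ST_INFUSION = 3,  // dx = kin/V 1(t<=tinf) + fC1(x) + (d/V) fC2(t)
  ST_MECH_ELIM = 4, // xA' = d fA1(t) - fA2(xA); xC' = fA2(xA) - kel xC
  ST_MECH_ABS = 5   // xA' = -ka xA, xA(0) = d/V
                    // xC' = ka xA - fC1(xC) - (d/V) fC2(t)
};

struct Net {
  int off;   // offset of W1 in the packed parameter vector
  int nin;   // 1 (conc or time input) or 2 (basic structure)
  int nhid;
  bool restr; // effective input weight is -(w^2)
};

struct ModelDesc {
  int structure;
  std::vector<Net> nets;
  bool hasV;
  int offV;      // offset of log(V)
  double kel, ka; // fixed mechanistic constants where used
  int dim;
  int npar;
};

struct Group {
  double d, kin, tinf;
  std::vector<double> grid;       // integration nodes, grid[0] = 0
  std::vector<int> obs_node;      // node index of each observation
  std::vector<double> obs_val;
};

static inline double eff_w(double w, bool restr) { return restr ? -(w * w) : w; }

// one-hidden-layer network, ReLU hidden / identity output, n_out = 1
static double mlp_eval(const double* th, const Net& nt, const double* x) {
  const double* W1 = th + nt.off;
  const double* b1 = W1 + nt.nhid * nt.nin;
  const double* W2 = b1 + nt.nhid;
  double out = W2[nt.nhid]; // b2
  for (int i = 0; i < nt.nhid; ++i) {
    double z = b1[i];
    for (int j = 0; j < nt.nin; ++j) z += eff_w(W1[i + nt.nhid * j], nt.restr) * x[j];
    if (z > 0) out += W2[i] * z;
  }
  return out;
}

// accumulate dL/dtheta into g and dL/dx into xbar, given bar = dL/dout
static void mlp_vjp(const double* th, const Net& nt, const double* x, double bar,
                    double* g, double* xbar) {
  const double* W1 = th + nt.off;
  const double* b1 = W1 + nt.nhid * nt.nin;
  const double* W2 = b1 + nt.nhid;
  double* gW1 = g + nt.off;
  double* gb1 = gW1 + nt.nhid * nt.nin;
  double* gW2 = gb1 + nt.nhid;
  gW2[nt.nhid] += bar; // b2
  for (int i = 0; i < nt.nhid; ++i) {
    double z = b1[i];
    for (int j = 0; j < nt.nin; ++j) z += eff_w(W1[i + nt.nhid * j], nt.restr) * x[j];
    if (z > 0) {
      gW2[i] += bar * z;
      double gz = bar * W2[i];
      gb1[i] += gz;
      for (int j = 0; j < nt.nin; ++j) {
        double w = W1[i + nt.nhid * j];
        double dwe = nt.restr ? -2.0 * w : 1.0;
        gW1[i + nt.nhid * j] += gz * x[j] * dwe;
        if (xbar) xbar[j] += gz * eff_w(w, nt.restr);
      }
    }
  }
}

// right-hand side; inf_on: infusion indicator resolved per integration
// interval (the grid always contains tinf as a node)
static void rhs(const ModelDesc& M, const double* th, double t, const double* y,
                const Group& G, bool inf_on, double* f) {
  switch (M.structure) {
  case ST_BASIC: {
    double x[2] = { y[0], t };
    f[0] = mlp_eval(th, M.nets[0], x);
    break;
  }
  case ST_SEPARATED: {
    double dV = G.d * std::exp(-th[M.offV]);
    f[0] = mlp_eval(th, M.nets[0], y) + dV * mlp_eval(th, M.nets[1], &t);
    break;
  }
  case ST_ABSORPTION: {
    double a1 = mlp_eval(th, M.nets[0], &t);
    double a2 = mlp_eval(th, M.nets[1], &y[0]);
    double c1 = mlp_eval(th, M.nets[2], &y[1]);
    double c2 = mlp_eval(th, M.nets[3], &t);
    f[0] = G.d * a1 - a2;
    f[1] = a2 - c1 - G.d * c2;
    break;
  }
  case ST_INFUSION: {
    double V = std::exp(th[M.offV]);
    f[0] = (inf_on ? G.kin / V : 0.0) + mlp_eval(th, M.nets[0], y)
         + (G.d / V) * mlp_eval(th, M.nets[1], &t);
    break;
  }
  case ST_MECH_ELIM: {
    double a1 = mlp_eval(th, M.nets[0], &t);
    double a2 = mlp_eval(th, M.nets[1], &y[0]);
    f[0] = G.d * a1 - a2;
    f[1] = a2 - M.kel * y[1];
    break;
  }
  case ST_MECH_ABS: {
    double dV = G.d * std::exp(-th[M.offV]);
    f[0] = -M.ka * y[0];
    f[1] = M.ka * y[0] - mlp_eval(th, M.nets[0], &y[1]) - dV * mlp_eval(th, M.nets[1], &t);
    break;
  }
  }
}

// reverse of rhs: given fbar = dL/df, accumulate dL/dtheta into g and add
// dL/dy into ybar
static void rhs_vjp(const ModelDesc& M, const double* th, double t, const double* y,
                    const Group& G, bool inf_on, const double* fbar,
                    double* g, double* ybar) {
  switch (M.structure) {
  case ST_BASIC: {
    double x[2] = { y[0], t };
    double xbar[2] = { 0.0, 0.0 };
    mlp_vjp(th, M.nets[0], x, fbar[0], g, xbar);
    ybar[0] += xbar[0];
    break;
  }
  case ST_SEPARATED: {
    double dV = G.d * std::exp(-th[M.offV]);
    mlp_vjp(th, M.nets[0], y, fbar[0], g, &ybar[0]);
    double c2 = mlp_eval(th, M.nets[1], &t);
    mlp_vjp(th, M.nets[1], &t, fbar[0] * dV, g, nullptr);
    g[M.offV] += fbar[0] * (-dV) * c2; // d(dV)/dlogV = -dV
    break;
  }
  case ST_ABSORPTION: {
    mlp_vjp(th, M.nets[0], &t, G.d * fbar[0], g, nullptr);
    mlp_vjp(th, M.nets[1], &y[0], fbar[1] - fbar[0], g, &ybar[0]);
    mlp_vjp(th, M.nets[2], &y[1], -fbar[1], g, &ybar[1]);
    mlp_vjp(th, M.nets[3], &t, -G.d * fbar[1], g, nullptr);
    break;
  }
  case ST_INFUSION: {
    double V = std::exp(th[M.offV]);
    mlp_vjp(th, M.nets[0], y, fbar[0], g, &ybar[0]);
    double c2 = mlp_eval(th, M.nets[1], &t);
    mlp_vjp(th, M.nets[1], &t, fbar[0] * G.d / V, g, nullptr);
    g[M.offV] += fbar[0] * (-(inf_on ? G.kin / V : 0.0) - (G.d / V) * c2);
    break;
  }
  case ST_MECH_ELIM: {
    mlp_vjp(th, M.nets[0], &t, G.d * fbar[0], g, nullptr);
    mlp_vjp(th, M.nets[1], &y[0], fbar[1] - fbar[0], g, &ybar[0]);
    ybar[1] += -M.kel * fbar[1];
    break;
  }
  case ST_MECH_ABS: {
    double dV = G.d * std::exp(-th[M.offV]);
    ybar[0] += -M.ka * fbar[0] + M.ka * fbar[1];
    mlp_vjp(th, M.nets[0], &y[1], -fbar[1], g, &ybar[1]);
    double c2 = mlp_eval(th, M.nets[1], &t);
    mlp_vjp(th, M.nets[1], &t, -fbar[1] * dV, g, nullptr);
    g[M.offV] += fbar[1] * dV * c2;
    break;
  }
  }
}

static void init_state(const ModelDesc& M, const double* th, const Group& G, double* y0) {
  double dV = M.hasV ? G.d * std::exp(-th[M.offV]) : 0.0;
  switch (M.structure) {
  case ST_BASIC:
  case ST_SEPARATED: y0[0] = dV; break;
  case ST_INFUSION:  y0[0] = 0.0; break;
  case ST_ABSORPTION:
  case ST_MECH_ELIM: y0[0] = 0.0; y0[1] = 0.0; break;
  case ST_MECH_ABS:  y0[0] = dV; y0[1] = 0.0; break;
  }
}

// dL/dlogV contribution of the initial condition, given ybar at t = 0
static double init_state_vjp(const ModelDesc& M, const double* th, const Group& G,
                             const double* ybar0) {
  if (!M.hasV) return 0.0;
  double dV = G.d * std::exp(-th[M.offV]);
  switch (M.structure) {
  case ST_BASIC:
  case ST_SEPARATED: return ybar0[0] * (-dV);
  case ST_MECH_ABS:  return ybar0[0] * (-dV);
  default: return 0.0;
  }
}

static inline bool interval_infusing(const ModelDesc& M, const Group& G,
                                     double t0, double t1) {
  if (M.structure != ST_INFUSION) return false;
  return 0.5 * (t0 + t1) <= G.tinf;
}

// forward solve over the group's grid; returns nodes x dim matrix of states
static bool forward_solve(const ModelDesc& M, const double* th, const Group& G,
                          std::vector<double>& Y) {
  const int n = (int)G.grid.size();
  const int dm = M.dim;
  Y.assign((size_t)n * dm, 0.0);
  double y[2], k1[2], k2[2], k3[2], k4[2], u[2];
  init_state(M, th, G, y);
  for (int j = 0; j < dm; ++j) Y[j] = y[j];
  for (int s = 0; s + 1 < n; ++s) {
    double t0 = G.grid[s], t1 = G.grid[s + 1], h = t1 - t0;
    bool inf_on = interval_infusing(M, G, t0, t1);
    rhs(M, th, t0, y, G, inf_on, k1);
    for (int j = 0; j < dm; ++j) u[j] = y[j] + 0.5 * h * k1[j];
    rhs(M, th, t0 + 0.5 * h, u, G, inf_on, k2);
    for (int j = 0; j < dm; ++j) u[j] = y[j] + 0.5 * h * k2[j];
    rhs(M, th, t0 + 0.5 * h, u, G, inf_on, k3);
    for (int j = 0; j < dm; ++j) u[j] = y[j] + h * k3[j];
    rhs(M, th, t1, u, G, inf_on, k4);
    for (int j = 0; j < dm; ++j) {
      y[j] += h / 6.0 * (k1[j] + 2.0 * k2[j] + 2.0 * k3[j] + k4[j]);
      if (!std::isfinite(y[j])) return false;
      Y[(size_t)(s + 1) * dm + j] = y[j];
    }
  }
  return true;
}

// loss of one group given its solved trajectory; seeds[node] receives
// dL/dpred at the central state for the reverse sweep
static double group_loss(const ModelDesc& M, const Group& G,
                         const std::vector<double>& Y, int loss_type, double inv_n,
                         std::vector<double>* seeds) {
  const int dm = M.dim;
  const int ic = dm - 1; // central state is the last component
  double L = 0.0;
  for (size_t o = 0; o < G.obs_node.size(); ++o) {
    double pred = Y[(size_t)G.obs_node[o] * dm + ic];
    double r = pred - G.obs_val[o];
    double w = (loss_type == 1) ? 1.0 / G.obs_val[o] : 1.0;
    L += w * r * r * inv_n;
    if (seeds) (*seeds)[G.obs_node[o]] += 2.0 * w * r * inv_n;
  }
  return L;
}

// reverse sweep accumulating dL/dtheta for one group
static void backward_sweep(const ModelDesc& M, const double* th, const Group& G,
                           const std::vector<double>& Y,
                           const std::vector<double>& seeds, double* g) {
  const int n = (int)G.grid.size();
  const int dm = M.dim;
  const int ic = dm - 1;
  double ybar[2] = { 0.0, 0.0 };
  ybar[ic] += seeds[n - 1];
  double y[2], k1[2], k2[2], k3[2], u2[2], u3[2], u4[2];
  double k1b[2], k2b[2], k3b[2], k4b[2], ub[2];
  for (int s = n - 2; s >= 0; --s) {
    double t0 = G.grid[s], t1 = G.grid[s + 1], h = t1 - t0;
    bool inf_on = interval_infusing(M, G, t0, t1);
    for (int j = 0; j < dm; ++j) y[j] = Y[(size_t)s * dm + j];
    // recompute stages
    rhs(M, th, t0, y, G, inf_on, k1);
    for (int j = 0; j < dm; ++j) u2[j] = y[j] + 0.5 * h * k1[j];
    rhs(M, th, t0 + 0.5 * h, u2, G, inf_on, k2);
    for (int j = 0; j < dm; ++j) u3[j] = y[j] + 0.5 * h * k2[j];
    rhs(M, th, t0 + 0.5 * h, u3, G, inf_on, k3);
    for (int j = 0; j < dm; ++j) u4[j] = y[j] + h * k3[j];
    // adjoint of ynew = y + h/6 (k1 + 2 k2 + 2 k3 + k4)
    for (int j = 0; j < dm; ++j) {
      k1b[j] = h / 6.0 * ybar[j];
      k2b[j] = h / 3.0 * ybar[j];
      k3b[j] = h / 3.0 * ybar[j];
      k4b[j] = h / 6.0 * ybar[j];
    }
    // stage 4: k4 = f(t1, u4), u4 = y + h k3
    for (int j = 0; j < dm; ++j) ub[j] = 0.0;
    rhs_vjp(M, th, t1, u4, G, inf_on, k4b, g, ub);
    for (int j = 0; j < dm; ++j) { ybar[j] += ub[j]; k3b[j] += h * ub[j]; }
    // stage 3: k3 = f(t0 + h/2, u3), u3 = y + h/2 k2
    for (int j = 0; j < dm; ++j) ub[j] = 0.0;
    rhs_vjp(M, th, t0 + 0.5 * h, u3, G, inf_on, k3b, g, ub);
    for (int j = 0; j < dm; ++j) { ybar[j] += ub[j]; k2b[j] += 0.5 * h * ub[j]; }
    // stage 2
    for (int j = 0; j < dm; ++j) ub[j] = 0.0;
    rhs_vjp(M, th, t0 + 0.5 * h, u2, G, inf_on, k2b, g, ub);
    for (int j = 0; j < dm; ++j) { ybar[j] += ub[j]; k1b[j] += 0.5 * h * ub[j]; }
    // stage 1
    rhs_vjp(M, th, t0, y, G, inf_on, k1b, g, ybar);
    // arrive at node s: add its observation seed
    ybar[ic] += seeds[s];
  }
  double gV = init_state_vjp(M, th, G, ybar);
  if (M.hasV) g[M.offV] += gV;
}

static ModelDesc parse_desc(const List& desc) {
  ModelDesc M;
  M.structure = as<int>(desc["structure"]);
  M.hasV = as<bool>(desc["has_v"]);
  M.kel = as<double>(desc["kel"]);
  M.ka = as<double>(desc["ka"]);
  M.dim = as<int>(desc["dim"]);
  List nets = desc["nets"];
  int off = 0;
  for (int i = 0; i < nets.size(); ++i) {
    List nl = nets[i];
    Net nt;
    nt.nin = as<int>(nl["n_in"]);
    nt.nhid = as<int>(nl["n_hid"]);
    nt.restr = as<bool>(nl["restrict"]);
    nt.off = off;
    off += nt.nhid * nt.nin + nt.nhid + nt.nhid + 1;
    M.nets.push_back(nt);
  }
  M.offV = M.hasV ? off : -1;
  M.npar = off + (M.hasV ? 1 : 0);
  return M;
}

static std::vector<Group> parse_groups(const List& groups) {
  std::vector<Group> gs;
  for (int i = 0; i < groups.size(); ++i) {
    List gl = groups[i];
    Group G;
    G.d = as<double>(gl["d"]);
    G.kin = as<double>(gl["kin"]);
    G.tinf = as<double>(gl["tinf"]);
    G.grid = as<std::vector<double> >(gl["grid"]);
    IntegerVector on = gl["obs_node"];
    G.obs_node = std::vector<int>(on.begin(), on.end());
    G.obs_val = as<std::vector<double> >(gl["obs_val"]);
    gs.push_back(G);
  }
  return gs;
}

static double total_obs(const std::vector<Group>& gs) {
  size_t n = 0;
  for (size_t i = 0; i < gs.size(); ++i) n += gs[i].obs_val.size();
  return (double)n;
}

// pooled loss + exact gradient of the discretized trajectory
static bool loss_and_grad(const ModelDesc& M, const std::vector<double>& th,
                          const std::vector<Group>& gs, int loss_type,
                          double& L, std::vector<double>& g) {
  L = 0.0;
  std::fill(g.begin(), g.end(), 0.0);
  double inv_n = 1.0 / total_obs(gs);
  std::vector<double> Y, seeds;
  for (size_t i = 0; i < gs.size(); ++i) {
    if (!forward_solve(M, th.data(), gs[i], Y)) return false;
    seeds.assign(gs[i].grid.size(), 0.0);
    L += group_loss(M, gs[i], Y, loss_type, inv_n, &seeds);
    backward_sweep(M, th.data(), gs[i], Y, seeds, g.data());
  }
  return std::isfinite(L);
}

// [[Rcpp::export]]
List node_engine_loss_grad(List desc, NumericVector theta, List groups, int loss_type) {
  ModelDesc M = parse_desc(desc);
  if ((int)theta.size() != M.npar) stop("theta has length %d, expected %d",
                                        (int)theta.size(), M.npar);
  std::vector<Group> gs = parse_groups(groups);
  std::vector<double> th(theta.begin(), theta.end()), g(M.npar, 0.0);
  double L;
  bool ok = loss_and_grad(M, th, gs, loss_type, L, g);
  return List::create(_["loss"] = ok ? L : NA_REAL,
                      _["grad"] = NumericVector(g.begin(), g.end()),
                      _["ok"] = ok);
}

// [[Rcpp::export]]
NumericMatrix node_engine_solve(List desc, NumericVector theta, List group) {
  ModelDesc M = parse_desc(desc);
  List gl = List::create(group);
  std::vector<Group> gs = parse_groups(gl);
  std::vector<double> th(theta.begin(), theta.end()), Y;
  if (!forward_solve(M, th.data(), gs[0], Y))
    stop("non-finite state encountered during integration");
  int n = (int)gs[0].grid.size();
  NumericMatrix out(n, M.dim);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < M.dim; ++j) out(i, j) = Y[(size_t)i * M.dim + j];
  return out;
}

// triangular cyclic schedule starting at lr_max, reaching lr_min mid-cycle
static double cyclic_lr(int epoch, double lr_min, double lr_max, int cycle) {
  int phase = (epoch - 1) % cycle;
  double frac = std::fabs(1.0 - 2.0 * (double)phase / (double)cycle);
  return lr_min + (lr_max - lr_min) * frac;
}

// [[Rcpp::export]]
List node_engine_train(List desc, NumericVector theta0, List groups, List cfg) {
  ModelDesc M = parse_desc(desc);
  std::vector<Group> gs = parse_groups(groups);
  const int epochs = as<int>(cfg["epochs"]);
  const double lr_min = as<double>(cfg["lr_min"]);
  const double lr_max = as<double>(cfg["lr_max"]);
  const int cycle = as<int>(cfg["cycle"]);
  const bool cyclic = as<bool>(cfg["cyclic"]);
  const bool track_best = as<bool>(cfg["track_best"]);
  const int loss_type = as<int>(cfg["loss_type"]);
  if ((int)theta0.size() != M.npar) stop("theta0 has length %d, expected %d",
                                         (int)theta0.size(), M.npar);

  std::vector<double> th(theta0.begin(), theta0.end());
  std::vector<double> g(M.npar, 0.0), m(M.npar, 0.0), v(M.npar, 0.0);
  std::vector<double> best_th(th);
  NumericVector history(epochs);
  double best_loss = R_PosInf;
  int best_epoch = NA_INTEGER;
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  int diverged_at = 0;

  for (int e = 1; e <= epochs; ++e) {
    double L;
    if (!loss_and_grad(M, th, gs, loss_type, L, g)) { diverged_at = e; break; }
    history[e - 1] = L;
    if (L < best_loss) { best_loss = L; best_epoch = e; if (track_best) best_th = th; }
    double lr = cyclic ? cyclic_lr(e, lr_min, lr_max, cycle) : lr_max;
    double bc1 = 1.0 - std::pow(b1, (double)e);
    double bc2 = 1.0 - std::pow(b2, (double)e);
    for (int p = 0; p < M.npar; ++p) {
      m[p] = b1 * m[p] + (1.0 - b1) * g[p];
      v[p] = b2 * v[p] + (1.0 - b2) * g[p] * g[p];
      th[p] -= lr * (m[p] / bc1) / (std::sqrt(v[p] / bc2) + eps);
    }
    if (e % 500 == 0) Rcpp::checkUserInterrupt();
  }

  if (!track_best) best_th = th;
  if (diverged_at > 0) {
    return List::create(_["ok"] = false, _["diverged_at"] = diverged_at,
                        _["loss_history"] = history[Range(0, std::max(0, diverged_at - 2))]);
  }
  return List::create(_["ok"] = true,
                      _["theta"] = NumericVector(best_th.begin(), best_th.end()),
                      _["theta_final"] = NumericVector(th.begin(), th.end()),
                      _["loss_history"] = history,
                      _["best_epoch"] = best_epoch,
                      _["final_loss"] = best_loss);
}
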