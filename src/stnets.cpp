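// Numerical core: cross-spectra accumulation over spike pairs, and the
// alternating-least-squares fit of the rank-one Hermitian network model
//   X[j1,j2,k,l] = sum_f a[j1,f] a[j2,f] exp(i 2 pi phi_k (s[j1,f]-s[j2,f]))
//                  * beta[k,f] * gamma[l,f]
// where beta and gamma are the squared frequency/trial profiles.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

static const double TWOPI = 6.283185307179586476925286766559;

// ---------------------------------------------------------------------------
// Cross spectra from spike sample indices.
//
// For two spikes at integer sample offset d = n2 - n1 with |d| < M, the full
// zero-padded convolution of each train with a unit-magnitude complex
// exponential of M samples contributes (M - |d|) * exp(-i 2 pi phi d / fs)
// to X[j1,j2]. Frequencies are integer multiples of their gcd, so phasors at
// all frequencies follow from one base rotation per pair by repeated
// multiplication.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
arma::cx_vec cross_spectra_cpp(const Rcpp::List& spikes, // trials -> neurons -> integer sample vectors (sorted)
                               int J, int M,
                               const arma::vec& freqs, double fs,
                               const arma::vec& durations,
                               bool scale_by_duration) {
  const int L = spikes.size();
  const int K = freqs.n_elem;
  // frequency multiples of the gcd implied by the base rotation
  double gcd = freqs(0);
  for (int k = 1; k < K; ++k) {
    double a = gcd, b = freqs(k);
    while (b > 1e-9) { double t = a - std::floor(a / b) * b; a = b; b = t; }
    gcd = a;
  }
  std::vector<int> mult(K);
  int mmax = 0;
  for (int k = 0; k < K; ++k) {
    mult[k] = (int) std::lround(freqs(k) / gcd);
    if (mult[k] > mmax) mmax = mult[k];
  }

  cx_vec X((size_t) J * J * K * L, fill::zeros);
  std::vector<cx_double> pw(mmax + 1);
  pw[0] = cx_double(1.0, 0.0);

  for (int l = 0; l < L; ++l) {
    Rcpp::List trial = spikes[l];
    std::vector<Rcpp::IntegerVector> tr(J);
    for (int j = 0; j < J; ++j) tr[j] = Rcpp::as<Rcpp::IntegerVector>(trial[j]);
    double sc = scale_by_duration ? 1.0 / durations(l) : 1.0;

    for (int j1 = 0; j1 < J; ++j1) {
      const Rcpp::IntegerVector& v1 = tr[j1];
      const int n1 = v1.size();
      if (n1 == 0) continue;
      for (int j2 = j1; j2 < J; ++j2) {
        const Rcpp::IntegerVector& v2 = tr[j2];
        const int n2 = v2.size();
        if (n2 == 0) continue;
        std::vector<cx_double> acc(K, cx_double(0.0, 0.0));
        int lo = 0;
        for (int i1 = 0; i1 < n1; ++i1) {
          const int s1 = v1[i1];
          while (lo < n2 && v2[lo] <= s1 - M) ++lo;
          for (int i2 = lo; i2 < n2; ++i2) {
            const int d = v2[i2] - s1;     // sample offset of j2 spike rel. j1 spike
            if (d >= M) break;
            const double w = (double)(M - std::abs(d));
            const double ang = -TWOPI * gcd * (double) d / fs;
            const cx_double base(std::cos(ang), std::sin(ang));
            for (int m = 1; m <= mmax; ++m) pw[m] = pw[m - 1] * base;
            for (int k = 0; k < K; ++k) acc[k] += w * pw[mult[k]];
          }
        }
        for (int k = 0; k < K; ++k) {
          const size_t off = ((size_t) l * K + k) * J * J;
          if (j2 == j1) {
            // diagonal pairs come in conjugate twins; imaginary parts
            // cancel analytically, so store the exact real power
            X(off + (size_t) j1 * J + j1) += sc * acc[k].real();
          } else {
            X(off + (size_t) j2 * J + j1) += sc * acc[k];
            X(off + (size_t) j1 * J + j2) += sc * std::conj(acc[k]);
          }
        }
      }
    }
  }
  return X;  // dim (J, J, K, L) column-major, j1 fastest
}

// ---------------------------------------------------------------------------
// Small nonnegative least squares on the normal equations:
// minimize 0.5 x'Gx - r'x subject to x >= 0 (Lawson-Hanson active set).
// ---------------------------------------------------------------------------
static vec nnls_gram_(const mat& G, const vec& r) {
  const uword n = r.n_elem;
  vec x(n, fill::zeros);
  uvec passive(n, fill::zeros);   // 1 = in passive (free) set
  double scale = std::max(1e-300, arma::abs(r).max() + G.diag().max());
  const double tol = 1e-12 * scale;

  for (uword outer = 0; outer < 10 * n + 20; ++outer) {
    vec w = r - G * x;            // negative gradient
    sword best = -1; double wbest = tol;
    for (uword i = 0; i < n; ++i)
      if (!passive(i) && w(i) > wbest) { wbest = w(i); best = i; }
    if (best < 0) break;
    passive(best) = 1;

    for (uword inner = 0; inner < 10 * n + 20; ++inner) {
      uvec P = find(passive == 1);
      vec z(n, fill::zeros);
      mat GP = G.submat(P, P);
      GP.diag() += 1e-14 * scale;
      vec zP;
      bool ok = solve(zP, GP, r.elem(P), solve_opts::likely_sympd + solve_opts::no_approx);
      if (!ok) zP = pinv(GP) * r.elem(P);
      z.elem(P) = zP;
      if (zP.min() > 0) { x = z; break; }
      // step toward z until first passive variable hits zero
      double alpha = 1.0; sword drop = -1;
      for (uword ii = 0; ii < P.n_elem; ++ii) {
        uword i = P(ii);
        if (z(i) <= 0) {
          double a = x(i) / (x(i) - z(i));
          if (a < alpha) { alpha = a; drop = i; }
        }
      }
      x += alpha * (z - x);
      if (drop >= 0) { passive(drop) = 0; x(drop) = 0.0; }
      x.elem(find(x < 0)).zeros();
    }
  }
  return x;
}

// [[Rcpp::export]]
arma::vec nnls_gram_cpp(const arma::mat& G, const arma::vec& r) {
  return nnls_gram_(G, r);
}

// ---------------------------------------------------------------------------
// ALS helpers
// ---------------------------------------------------------------------------

// spatial vectors u[j,k] = a[j] exp(i 2 pi phi_k s[j]) for one component
static cx_mat make_u(const vec& a, const vec& s, const vec& freqs) {
  const uword J = a.n_elem, K = freqs.n_elem;
  cx_mat U(J, K);
  for (uword k = 0; k < K; ++k)
    for (uword j = 0; j < J; ++j) {
      double ang = TWOPI * freqs(k) * s(j);
      U(j, k) = a(j) * cx_double(std::cos(ang), std::sin(ang));
    }
  return U;
}

// block objective for the spatial/time step of component f (up to a constant):
// Q(u) = -2 sum_k beta_k Re(u_k^H H_k u_k) + ctc_ff * sum_k beta_k^2 ||u_k||^4
static double block_obj(const cx_mat& U, const cx_cube& H, const vec& beta,
                        double ctcff) {
  double q = 0.0;
  for (uword k = 0; k < H.n_slices; ++k) {
    const cx_vec u = U.col(k);
    double quad = std::real(cdot(u, H.slice(k) * u));
    double nn = std::real(cdot(u, u));
    q += -2.0 * beta(k) * quad + ctcff * beta(k) * beta(k) * nn * nn;
  }
  return q;
}

// one coordinate-descent pass on the constrained block objective
//   Q(a, s) = -2 a^T M(s) a + ctcff * sum_k beta_k^2 * (a^T a)^2
// with M(s) = sum_k beta_k Re(Phi_k^H H_k Phi_k), Phi_k = diag(exp(i 2pi f_k s)):
// exact a-step via the leading eigenpair of M(s), then per-neuron s-step by
// grid search plus golden refinement (declared below).
static void refine_block(vec& a, vec& s, const cx_cube& H, const vec& beta,
                         double ctcff, const vec& freqs, const vec& grid,
                         const cx_mat& GphC, double period, int passes);

// phase-alignment objective for one neuron: h(s) = Re(sum_k w_k exp(-i 2pi f_k s))
static double phase_obj(const cx_rowvec& w, const vec& freqs, double s) {
  double v = 0.0;
  for (uword k = 0; k < freqs.n_elem; ++k) {
    double ang = -TWOPI * freqs(k) * s;
    v += std::real(w(k) * cx_double(std::cos(ang), std::sin(ang)));
  }
  return v;
}

static double grid_then_golden(const cx_rowvec& w, const vec& freqs,
                               const vec& grid, const cx_mat& Gph,
                               double period);

static double golden_refine(const cx_rowvec& w, const vec& freqs,
                            double lo, double hi, int iters = 25) {
  const double gr = 0.61803398874989484820;
  double a = lo, b = hi;
  double c = b - gr * (b - a), d = a + gr * (b - a);
  double fc = phase_obj(w, freqs, c), fd = phase_obj(w, freqs, d);
  for (int it = 0; it < iters; ++it) {
    if (fc > fd) { b = d; d = c; fd = fc; c = b - gr * (b - a); fc = phase_obj(w, freqs, c); }
    else { a = c; c = d; fc = fd; d = a + gr * (b - a); fd = phase_obj(w, freqs, d); }
  }
  return 0.5 * (a + b);
}

// GphC holds conj(exp(i 2 pi f g)) precomputed for the grid
static double grid_then_golden(const cx_rowvec& w, const vec& freqs,
                               const vec& grid, const cx_mat& GphC,
                               double period) {
  rowvec obj = real(w * GphC);
  uword g = obj.index_max();
  double step = period / grid.n_elem;
  return golden_refine(w, freqs, grid(g) - step, grid(g) + step);
}

static void refine_block(vec& a, vec& s, const cx_cube& H, const vec& beta,
                         double ctcff, const vec& freqs, const vec& grid,
                         const cx_mat& GphC, double period, int passes) {
  const uword J = a.n_elem, K = beta.n_elem;
  const double Cc = ctcff * dot(beta, beta);
  for (int pass = 0; pass < passes; ++pass) {
    // exact magnitude step: leading eigenpair of the phase-rotated form
    mat M(J, J, fill::zeros);
    for (uword k = 0; k < K; ++k) {
      if (beta(k) == 0) continue;
      cx_vec ph(J);
      for (uword j = 0; j < J; ++j) {
        double ang = TWOPI * freqs(k) * s(j);
        ph(j) = cx_double(std::cos(ang), std::sin(ang));
      }
      const cx_mat& Hk = H.slice(k);
      for (uword j1 = 0; j1 < J; ++j1)
        for (uword j2 = 0; j2 < J; ++j2)
          M(j1, j2) += beta(k) *
            std::real(std::conj(ph(j1)) * Hk(j1, j2) * ph(j2));
    }
    M = 0.5 * (M + M.t());          // exact symmetry for eig_sym
    vec ev; mat evec;
    if (!eig_sym(ev, evec, M)) return;
    double lam = ev(J - 1);
    if (lam <= 0 || Cc <= 0) return;   // leave candidate as passed in
    a = std::sqrt(lam / Cc) * evec.col(J - 1);
    if (mean(a) < 0) a = -a;
    // per-neuron time step, Gauss-Seidel: H u kept current through
    // rank-one updates as each neuron's coefficient moves
    cx_mat U = make_u(a, s, freqs);
    cx_mat HU(J, K);
    for (uword k = 0; k < K; ++k) HU.col(k) = H.slice(k) * U.col(k);
    for (uword j = 0; j < J; ++j) {
      if (a(j) == 0) continue;
      cx_rowvec w(K);
      for (uword k = 0; k < K; ++k) {
        cx_double b = HU(j, k) - H.slice(k)(j, j) * U(j, k);
        w(k) = beta(k) * a(j) * b;
      }
      s(j) = grid_then_golden(w, freqs, grid, GphC, period);
      for (uword k = 0; k < K; ++k) {
        double ang = TWOPI * freqs(k) * s(j);
        cx_double unew = a(j) * cx_double(std::cos(ang), std::sin(ang));
        cx_double delta = unew - U(j, k);
        if (delta != cx_double(0.0, 0.0))
          HU.col(k) += H.slice(k).col(j) * delta;
        U(j, k) = unew;
      }
    }
  }
}

// ---------------------------------------------------------------------------
// ALS fit for one initialization.
// Xm: (J*J*K) x L complex, column l holds vec of (J x J x K) with j1 fastest.
// ---------------------------------------------------------------------------
static Rcpp::List als_one(const cx_mat& Xm, const vec& freqs, int J, int F,
                          mat A, mat S, mat B, mat C,
                          double tol, int max_iter,
                          double period, double grid_step) {
  const int K = freqs.n_elem;
  const int L = Xm.n_cols;
  const double normX2 = accu(square(abs(Xm)));

  // sigma grid over one cycle (-period/2, period/2]
  const int nG = std::max(8, (int) std::lround(period / grid_step));
  vec grid(nG);
  for (int g = 0; g < nG; ++g) grid(g) = -period / 2.0 + period * (g + 1.0) / nG;
  cx_mat Gph(K, nG);
  for (int k = 0; k < K; ++k)
    for (int g = 0; g < nG; ++g) {
      double ang = TWOPI * freqs(k) * grid(g);
      Gph(k, g) = cx_double(std::cos(ang), std::sin(ang));
    }
  const cx_mat GphC = conj(Gph);
  // coarser localization grid for the refinement passes (0.1 ms class);
  // golden-section search supplies the final resolution
  const int nGc = std::max(8, nG / 10);
  vec gridc(nGc);
  for (int g = 0; g < nGc; ++g)
    gridc(g) = -period / 2.0 + period * (g + 1.0) / nGc;
  cx_mat GphcC(K, nGc);
  for (int k = 0; k < K; ++k)
    for (int g = 0; g < nGc; ++g) {
      double ang = -TWOPI * freqs(k) * gridc(g);
      GphcC(k, g) = cx_double(std::cos(ang), std::sin(ang));
    }

  std::vector<cx_mat> U(F);
  for (int f = 0; f < F; ++f) U[f] = make_u(A.col(f), S.col(f), freqs);

  // reordered copy of the tensor with layout (j1, j2, l, k): for a fixed
  // frequency the J x (J*L) block is contiguous, so the per-trial
  // quadratic forms Re(u^H X_kl u) become two BLAS products per (f, k)
  cx_mat Xr(J * (size_t) J * L, K);
  for (int l = 0; l < L; ++l)
    for (int k = 0; k < K; ++k)
      std::memcpy(Xr.colptr(k) + (size_t) l * J * J,
                  Xm.colptr(l) + (size_t) k * J * J,
                  sizeof(cx_double) * J * J);

  double loss = datum::inf, loss_prev = datum::inf;
  int iter = 0; bool converged = false;
  double worst_increase = 0.0;

  cx_cube Hf(J, J, K);           // scratch: weighted residual matrices for one f
  mat Gg(F, F, fill::zeros);     // gram for gamma step
  cube sklf(K, L, F);            // Re(u^H X_kl u)

  for (iter = 1; iter <= max_iter; ++iter) {
    const cx_mat XC = Xm * conv_to<cx_mat>::from(C);   // (J*J*K) x F
    const mat CtC = C.t() * C;
    cx_vec Xsum;                                        // lazy: sum over trials

    // ---- spatial/time block, per component with deflation ----
    for (int f = 0; f < F; ++f) {
      // a dead component (zero frequency or trial profile) would be frozen:
      // give it uniform frequency weights and uniform trial weights for its
      // own residual view so it can re-grab structure left unexplained
      vec bf = B.col(f);
      if (accu(bf) <= 0) bf.ones();
      const bool gammaDead = CtC(f, f) <= 0;
      vec cf_dot(F);                  // <gamma_f', gamma_g> couplings
      double cff;
      if (gammaDead) {
        if (Xsum.n_elem == 0) Xsum = sum(Xm, 1);
        for (int g = 0; g < F; ++g) cf_dot(g) = accu(C.col(g));
        cff = (double) L;
      } else {
        for (int g = 0; g < F; ++g) cf_dot(g) = CtC(f, g);
        cff = CtC(f, f);
      }
      cx_mat W(J, K, fill::zeros);
      for (int k = 0; k < K; ++k) {
        cx_mat Y = gammaDead
          ? cx_mat((cx_double*) Xsum.memptr() + (size_t) k * J * J, J, J)
          : cx_mat((cx_double*) XC.colptr(f) + (size_t) k * J * J, J, J);
        for (int g = 0; g < F; ++g) {
          if (g == f) continue;
          Y -= (cf_dot(g) * B(k, g)) * (U[g].col(k) * U[g].col(k).t());
        }
        cx_mat H = 0.5 * (Y + Y.t());
        Hf.slice(k) = H;
        double denom = bf(k) * cff;
        if (denom > 1e-300) {
          vec eval; cx_mat evec;
          if (eig_sym(eval, evec, H)) {
            double lam = eval(J - 1);
            if (lam > 0) W.col(k) = std::sqrt(lam / denom) * evec.col(J - 1);
          }
        }
      }
      // align per-frequency eigenvector phases to the strongest neuron
      mat mags = abs(W);
      vec rowsum = sum(mags, 1);
      uword ref = rowsum.index_max();
      cx_rowvec refph(K);
      rowvec refmag = mags.row(ref);
      for (int k = 0; k < K; ++k) {
        double m = refmag(k);
        refph(k) = (m > 0) ? W(ref, k) / m : cx_double(1.0, 0.0);
      }
      cx_mat Wt = W;
      for (int k = 0; k < K; ++k) Wt.col(k) *= std::conj(refph(k));
      cx_mat Wobj = Wt;
      for (int k = 0; k < K; ++k) Wobj.col(k) *= refmag(k);

      mat Obj = real(Wobj * GphC);        // J x nG
      vec anew(J, fill::zeros), snew(J, fill::zeros);
      uvec active = find(sum(mags, 0).t() > 0);  // frequencies with signal
      for (int j = 0; j < J; ++j) {
        uword g = Obj.row(j).index_max();
        double lo = grid(g) - period / nG, hi = grid(g) + period / nG;
        double sj = golden_refine(Wobj.row(j), freqs, lo, hi);
        snew(j) = sj;
        if (active.n_elem > 0) {
          double aj = 0.0;
          for (uword kk = 0; kk < active.n_elem; ++kk) {
            uword k = active(kk);
            double ang = -TWOPI * freqs(k) * sj;
            aj += std::real(Wt(j, k) * cx_double(std::cos(ang), std::sin(ang)));
          }
          anew(j) = aj / active.n_elem;
        }
      }
      // coordinate-descent refinement of both candidates on the exact
      // constrained block objective, then keep the best of three
      refine_block(anew, snew, Hf, bf, cff, freqs, gridc, GphcC, period, 2);
      vec acur = A.col(f), scur = S.col(f);
      refine_block(acur, scur, Hf, bf, cff, freqs, gridc, GphcC, period, 1);
      cx_mat Unew = make_u(anew, snew, freqs);
      cx_mat Ucur = make_u(acur, scur, freqs);
      double qold = block_obj(U[f], Hf, bf, cff);
      double qnew = block_obj(Unew, Hf, bf, cff);
      double qcur = block_obj(Ucur, Hf, bf, cff);
      if (qnew <= qold && qnew <= qcur) {
        A.col(f) = anew; S.col(f) = snew; U[f] = Unew;
      } else if (qcur <= qold) {
        A.col(f) = acur; S.col(f) = scur; U[f] = Ucur;
      }
    }

    // model-neutral revival of dead components: when the product of the
    // squared frequency and trial profiles is zero, reset to uniform
    // frequency weights and zero trial weights (the model is unchanged);
    // the trial update below can then bring the component back
    for (int f = 0; f < F; ++f)
      if (accu(B.col(f)) <= 0 || accu(C.col(f)) <= 0) {
        C.col(f).zeros();
        B.col(f).ones();
      }

    // cross-component spatial grams per frequency: |u_kf^H u_kg|^2
    cube UU(F, F, K);
    for (int k = 0; k < K; ++k)
      for (int f = 0; f < F; ++f)
        for (int g = f; g < F; ++g) {
          double v = std::norm(cdot(U[f].col(k), U[g].col(k)));
          UU(f, g, k) = v; UU(g, f, k) = v;
        }

    // quadratic forms Re(u^H X_kl u), shared by both profile updates
    for (int k = 0; k < K; ++k) {
      const cx_mat Xk((cx_double*) Xr.colptr(k), J, (size_t) J * L, false);
      for (int f = 0; f < F; ++f) {
        cx_rowvec v = U[f].col(k).t() * Xk;          // conj-transpose row
        const cx_mat Vm((cx_double*) v.memptr(), J, L, false);
        cx_rowvec sv = U[f].col(k).st() * Vm;
        for (int l = 0; l < L; ++l) sklf(k, l, f) = sv(l).real();
      }
    }

    // ---- gamma (squared trial profile), per-trial NNLS ----
    for (int f = 0; f < F; ++f)
      for (int g = 0; g < F; ++g) {
        double v = 0.0;
        for (int k = 0; k < K; ++k) v += B(k, f) * B(k, g) * UU(f, g, k);
        Gg(f, g) = v;
      }
    for (int l = 0; l < L; ++l) {
      vec rl(F);
      for (int f = 0; f < F; ++f) {
        double v = 0.0;
        for (int k = 0; k < K; ++k) v += B(k, f) * sklf(k, l, f);
        rl(f) = v;
      }
      C.row(l) = nnls_gram_(Gg, rl).t();
    }

    // ---- beta (squared frequency profile), per-frequency NNLS ----
    const mat CtC2 = C.t() * C;
    for (int k = 0; k < K; ++k) {
      mat Gk(F, F);
      vec rk(F);
      for (int f = 0; f < F; ++f) {
        for (int g = 0; g < F; ++g) Gk(f, g) = UU(f, g, k) * CtC2(f, g);
        double v = 0.0;
        for (int l = 0; l < L; ++l) v += C(l, f) * sklf(k, l, f);
        rk(f) = v;
      }
      B.row(k) = nnls_gram_(Gk, rk).t();
    }

    // ---- loss (with the post-update profiles) ----
    double ip = 0.0;
    for (int f = 0; f < F; ++f)
      for (int k = 0; k < K; ++k) {
        double v = 0.0;
        for (int l = 0; l < L; ++l) v += C(l, f) * sklf(k, l, f);
        ip += B(k, f) * v;
      }
    for (int f = 0; f < F; ++f)
      for (int g = 0; g < F; ++g) {
        double v = 0.0;
        for (int k = 0; k < K; ++k) v += B(k, f) * B(k, g) * UU(f, g, k);
        Gg(f, g) = v;
      }
    double nh2 = accu(CtC2 % Gg);
    loss = normX2 - 2.0 * ip + nh2;

    if (std::isfinite(loss_prev)) {
      double inc = (loss - loss_prev) / std::max(1e-300, normX2);
      if (inc > worst_increase) worst_increase = inc;
      if (std::abs(loss_prev - loss) / std::max(loss_prev, 1e-300) < tol) {
        converged = true;
        break;
      }
    }
    loss_prev = loss;
  }

  return Rcpp::List::create(
    Rcpp::Named("A") = A, Rcpp::Named("S") = S,
    Rcpp::Named("B") = B, Rcpp::Named("C") = C,
    Rcpp::Named("loss") = loss,
    Rcpp::Named("normX2") = normX2,
    Rcpp::Named("iterations") = std::min(iter, max_iter),
    Rcpp::Named("converged") = converged,
    Rcpp::Named("worst_increase") = worst_increase);
}

// [[Rcpp::export]]
Rcpp::List space_als_cpp(const arma::cx_mat& Xm, const arma::vec& freqs,
                         int J, int F, const Rcpp::List& inits,
                         double tol, int max_iter,
                         double period, double grid_step) {
  const int n_init = inits.size();
  Rcpp::List out(n_init);
  for (int i = 0; i < n_init; ++i) {
    Rcpp::List ini = inits[i];
    out[i] = als_one(Xm, freqs, J, F,
                     Rcpp::as<mat>(ini["A"]), Rcpp::as<mat>(ini["S"]),
                     Rcpp::as<mat>(ini["B"]), Rcpp::as<mat>(ini["C"]),
                     tol, max_iter, period, grid_step);
    Rcpp::checkUserInterrupt();
  }
  return out;
}
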