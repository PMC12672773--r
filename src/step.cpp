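#include <Rcpp.h>
using namespace Rcpp;

// Agent state codes, matching STATE_CODES on the R side.
static const int EMPTY = 0, TUMOR = 1, ANTI = 2, PRO = 3;

// Thomas algorithm for a constant-coefficient tridiagonal system
// (diag b, off-diagonals a/c supplied per index). Overwrites rhs with the
// solution.
static void thomas(std::vector<double>& sub, std::vector<double>& diag,
                   std::vector<double>& sup, std::vector<double>& rhs) {
  const int n = (int)rhs.size();
  for (int i = 1; i < n; ++i) {
    double w = sub[i] / diag[i - 1];
    diag[i] -= w * sup[i - 1];
    rhs[i] -= w * rhs[i - 1];
  }
  rhs[n - 1] /= diag[n - 1];
  for (int i = n - 2; i >= 0; --i)
    rhs[i] = (rhs[i] - sup[i] * rhs[i + 1]) / diag[i];
}

// Backward-Euler solve of (I - R d2/dx2) u = rhs along one line.
// neumann: reflecting ends; otherwise both end values are pinned to cb and
// only the interior is solved.
static void solve_line(std::vector<double>& u, double R, bool neumann,
                       double cb) {
  const int n = (int)u.size();
  if (R <= 0.0) {
    if (!neumann && n >= 1) { u[0] = cb; u[n - 1] = cb; }
    return;
  }
  if (neumann) {
    std::vector<double> sub(n, -R), diag(n, 1 + 2 * R), sup(n, -R), rhs(u);
    diag[0] = 1 + R; diag[n - 1] = 1 + R;
    thomas(sub, diag, sup, rhs);
    u = rhs;
  } else {
    if (n <= 2) { for (int i = 0; i < n; ++i) u[i] = cb; return; }
    const int m = n - 2;
    std::vector<double> sub(m, -R), diag(m, 1 + 2 * R), sup(m, -R), rhs(m);
    for (int i = 0; i < m; ++i) rhs[i] = u[i + 1];
    rhs[0] += R * cb; rhs[m - 1] += R * cb;
    thomas(sub, diag, sup, rhs);
    u[0] = cb; u[n - 1] = cb;
    for (int i = 0; i < m; ++i) u[i + 1] = rhs[i];
  }
}

// One alternating-direction implicit diffusion step: a column-implicit
// sweep over every row, then a row-implicit sweep over every column, each
// backward-Euler over dt/substeps. Dirichlet cb boundaries while dosing,
// Neumann (or absorbing) otherwise.
static void adi_inplace(NumericMatrix C, double Dc, bool dirichlet,
                        double cb, int substeps, bool rest_neumann) {
  const int nr = C.nrow(), nc = C.ncol();
  const bool neumann = !dirichlet && rest_neumann;
  const double bc_val = dirichlet ? cb : 0.0;
  if (substeps < 1) substeps = 1;
  const double R = Dc / (double)substeps;
  for (int s = 0; s < substeps; ++s) {
    if (!neumann) {
      for (int j = 0; j < nc; ++j) { C(0, j) = bc_val; C(nr - 1, j) = bc_val; }
      for (int i = 0; i < nr; ++i) { C(i, 0) = bc_val; C(i, nc - 1) = bc_val; }
    }
    // sweep 1: implicit along columns (solve each row)
    std::vector<double> line;
    int i0 = neumann ? 0 : 1, i1 = neumann ? nr : nr - 1;
    for (int i = i0; i < i1; ++i) {
      line.assign(nc, 0.0);
      for (int j = 0; j < nc; ++j) line[j] = C(i, j);
      solve_line(line, R, neumann, bc_val);
      for (int j = 0; j < nc; ++j) C(i, j) = line[j];
    }
    // sweep 2: implicit along rows (solve each column)
    int j0 = neumann ? 0 : 1, j1 = neumann ? nc : nc - 1;
    for (int j = j0; j < j1; ++j) {
      line.assign(nr, 0.0);
      for (int i = 0; i < nr; ++i) line[i] = C(i, j);
      solve_line(line, R, neumann, bc_val);
      for (int i = 0; i < nr; ++i) C(i, j) = line[i];
    }
    for (int i = 0; i < nr; ++i)
      for (int j = 0; j < nc; ++j)
        if (C(i, j) < 0) C(i, j) = 0;
  }
}

// [[Rcpp::export]]
NumericMatrix adi_cpp(NumericMatrix drug, double Dc, bool dosing, double cb,
                      int substeps, bool rest_neumann) {
  NumericMatrix C = clone(drug);
  adi_inplace(C, Dc, dosing, cb, substeps, rest_neumann);
  return C;
}

// Fisher-Yates shuffle driven by R's RNG stream.
static void shuffle_idx(std::vector<int>& v) {
  for (int i = (int)v.size() - 1; i >= 1; --i) {
    int j = (int)(unif_rand() * (i + 1));
    if (j > i) j = i;
    std::swap(v[i], v[j]);
  }
}

// One full model step: astrocyte switching sweep, tumor division/death
// sweep, then the drug-field update. Consumes R's RNG stream; the caller
// (advance_step) owns step accounting and therapy triggering.
// [[Rcpp::export]]
List step_cpp(IntegerMatrix states_in, NumericMatrix drug_in,
              IntegerVector off_dr, IntegerVector off_dc,
              NumericVector off_w,
              double alpha, double beta, double theta, double kappa,
              double SA, double ST, double i_max,
              bool switching_enabled,
              bool has_chemo, bool dosing,
              double Dc, double decay_factor, double cb,
              double uptake_fraction, double Gf, double kkill, double Thalf,
              int substeps, bool rest_neumann) {
  IntegerMatrix states = clone(states_in); // RNGScope supplied by the wrapper
  NumericMatrix drug = clone(drug_in);
  const int nr = states.nrow(), nc = states.ncol();
  const int noff = off_dr.size();

  // radius of the interaction neighborhood (offsets span [-rad, rad])
  int rad = 0;
  for (int o = 0; o < noff; ++o) {
    if (std::abs(off_dr[o]) > rad) rad = std::abs(off_dr[o]);
    if (std::abs(off_dc[o]) > rad) rad = std::abs(off_dc[o]);
  }
  // linear offsets for the interior fast path (no bounds checks needed)
  std::vector<int> off_lin(noff);
  for (int o = 0; o < noff; ++o) off_lin[o] = off_dr[o] + off_dc[o] * nr;
  int* st_ptr = states.begin();

  std::vector<int> anti, tumors;
  anti.reserve(1024); tumors.reserve(1024);
  for (int idx = 0; idx < nr * nc; ++idx) {
    int st = st_ptr[idx];
    if (st == ANTI) anti.push_back(idx);
    else if (st == TUMOR) tumors.push_back(idx);
  }

  // --- astrocyte sweep -------------------------------------------------
  // Tumor positions are static during this sweep, so the cumulative tumor
  // influence field can be deposited once: each tumor cell adds its
  // distance weight (magnitude kappa) to every site of its neighborhood.
  int n_switched = 0;
  if (switching_enabled) {
    NumericMatrix ftum(nr, nc);
    double* ft = ftum.begin();
    for (size_t t = 0; t < tumors.size(); ++t) {
      int idx = tumors[t], i = idx % nr, j = idx / nr;
      if (i >= rad && i < nr - rad && j >= rad && j < nc - rad) {
        for (int o = 0; o < noff; ++o) ft[idx + off_lin[o]] += kappa * off_w[o];
      } else {
        for (int o = 0; o < noff; ++o) {
          int r = i + off_dr[o], c = j + off_dc[o];
          if (r >= 0 && r < nr && c >= 0 && c < nc)
            ft[r + c * nr] += kappa * off_w[o];
        }
      }
    }
    const double p_leak = 1.0 / (1.0 + std::exp(SA * theta));
    shuffle_idx(anti);
    for (size_t a = 0; a < anti.size(); ++a) {
      int idx = anti[a];
      double p;
      if (ft[idx] == 0.0) {
        p = p_leak;
      } else {
        double inorm = ft[idx] / i_max;
        if (inorm > 1.0) inorm = 1.0;
        p = 1.0 / (1.0 + std::exp(-SA * (inorm - theta)));
      }
      if (unif_rand() < p) { st_ptr[idx] = PRO; ++n_switched; }
    }
  }

  // --- tumor sweep -----------------------------------------------------
  // Astrocyte phenotypes are now fixed for the remainder of the step, so
  // each tumor cell's signed influence is gathered from its neighborhood
  // on its turn.
  shuffle_idx(tumors);

  static const int mdr[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  static const int mdc[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  int n_births = 0, n_deaths = 0;
  for (size_t t = 0; t < tumors.size(); ++t) {
    int idx = tumors[t], i = idx % nr, j = idx / nr;
    double infl = 0.0;
    if (i >= rad && i < nr - rad && j >= rad && j < nc - rad) {
      for (int o = 0; o < noff; ++o) {
        int st = st_ptr[idx + off_lin[o]];
        if (st == ANTI) infl -= alpha * off_w[o];
        else if (st == PRO) infl += beta * off_w[o];
      }
    } else {
      for (int o = 0; o < noff; ++o) {
        int r = i + off_dr[o], c = j + off_dc[o];
        if (r >= 0 && r < nr && c >= 0 && c < nc) {
          int st = st_ptr[r + c * nr];
          if (st == ANTI) infl -= alpha * off_w[o];
          else if (st == PRO) infl += beta * off_w[o];
        }
      }
    }
    double inorm = infl / i_max;
    if (inorm > 1.0) inorm = 1.0;
    if (inorm < -1.0) inorm = -1.0;
    double pdiv = 1.0 / (1.0 + std::exp(-ST * inorm));
    double u = unif_rand();
    if (u < pdiv) {
      int er[8], ec[8], k = 0;
      for (int o = 0; o < 8; ++o) {
        int r = i + mdr[o], c = j + mdc[o];
        if (r >= 0 && r < nr && c >= 0 && c < nc && states(r, c) == EMPTY) {
          er[k] = r; ec[k] = c; ++k;
        }
      }
      if (k > 0) {
        int pick = (int)(unif_rand() * k);
        if (pick >= k) pick = k - 1;
        states(er[pick], ec[pick]) = TUMOR;
        ++n_births;
      }
    }
    if (has_chemo && dosing) {
      int npro = 0;
      for (int o = 0; o < 8; ++o) {
        int r = i + mdr[o], c = j + mdc[o];
        if (r >= 0 && r < nr && c >= 0 && c < nc && states(r, c) == PRO)
          ++npro;
      }
      double ceff = drug(i, j) * (1.0 - Gf * npro / 8.0);
      if (ceff < 0) ceff = 0;
      double pdeath = 1.0 / (1.0 + std::exp(-kkill * (ceff - Thalf)));
      if (unif_rand() < pdeath) { states(i, j) = EMPTY; ++n_deaths; }
    }
  }

  // --- drug field ------------------------------------------------------
  if (has_chemo) {
    adi_inplace(drug, Dc, dosing, cb, substeps, rest_neumann);
    for (int j = 0; j < nc; ++j)
      for (int i = 0; i < nr; ++i) {
        double v = drug(i, j) * decay_factor;
        if (states(i, j) == TUMOR) v *= (1.0 - uptake_fraction);
        drug(i, j) = v < 0 ? 0 : v;
      }
  }

  return List::create(_["states"] = states, _["drug"] = drug,
                      _["births"] = n_births, _["deaths"] = n_deaths,
                      _["switches"] = n_switched);
}
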