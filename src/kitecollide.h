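#ifndef KITECOLLIDE_H
#define KITECOLLIDE_H

double pt_ellipsoid(const double* p, const double* a, double* cp, bool* inside);
double seg_ellipsoid(const double* p0, const double* p1, const double* a,
                     double* seg_pt, double* ell_pt);
double mesh_ellipsoid(const double* V, int nv, const int* F, int nf,
                      const double* a, double* mesh_pt, double* ell_pt,
                      int* n_degenerate);

#endif
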