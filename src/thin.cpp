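#include <Rcpp.h>
using namespace Rcpp;

// One Guo-Hall subiteration; returns number of deleted pixels.
static int thin_iter(IntegerMatrix im, int iter) {
  int nr = im.nrow(), nc = im.ncol();
  IntegerMatrix marker(nr, nc);
  int deleted = 0;
  for (int i = 1; i < nr - 1; i++) {
    for (int j = 1; j < nc - 1; j++) {
      if (!im(i, j)) continue;
      int p2 = im(i - 1, j),     p3 = im(i - 1, j + 1);
      int p4 = im(i, j + 1),     p5 = im(i + 1, j + 1);
      int p6 = im(i + 1, j),     p7 = im(i + 1, j - 1);
      int p8 = im(i, j - 1),     p9 = im(i - 1, j - 1);
      int C  = ((!p2) & (p3 | p4)) + ((!p4) & (p5 | p6)) +
               ((!p6) & (p7 | p8)) + ((!p8) & (p9 | p2));
      int N1 = (p9 | p2) + (p3 | p4) + (p5 | p6) + (p7 | p8);
      int N2 = (p2 | p3) + (p4 | p5) + (p6 | p7) + (p8 | p9);
      int N  = N1 < N2 ? N1 : N2;
      int m  = iter == 0 ? ((p6 | p7 | (!p9)) & p8)
                         : ((p2 | p3 | (!p5)) & p4);
      if (C == 1 && N >= 2 && N <= 3 && m == 0) {
        marker(i, j) = 1;
        deleted++;
      }
    }
  }
  if (deleted > 0)
    for (int i = 0; i < nr; i++)
      for (int j = 0; j < nc; j++)
        if (marker(i, j)) im(i, j) = 0;
  return deleted;
}

// Guo-Hall morphological thinning of a binary image to a 1-px skeleton.
// Border pixels are treated as background (mask objects are expected not to
// fill the full frame).
// [[Rcpp::export(name = ".thin_guo_hall")]]
IntegerMatrix thin_guo_hall(IntegerMatrix mask) {
  IntegerMatrix im = clone(mask);
  int nr = im.nrow(), nc = im.ncol();
  for (int i = 0; i < nr; i++) { im(i, 0) = 0; im(i, nc - 1) = 0; }
  for (int j = 0; j < nc; j++) { im(0, j) = 0; im(nr - 1, j) = 0; }
  int changed = 1;
  while (changed) {
    changed  = thin_iter(im, 0);
    changed += thin_iter(im, 1);
  }
  return im;
}
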