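written by LipidSites
152
    1BB      BB    1  18.913  10.000   3.000
    2BB      BB    2  18.885  10.699   3.000
    3BB      BB    3  18.803  11.394   3.000
    4BB      BB    4  18.666  12.081   3.000
    5BB      BB    5  18.476  12.754   3.000
    6BB      BB    6  18.234  13.411   3.000
    7BB      BB    7  17.941  14.046   3.000
    8BB      BB    8  17.599  14.657   3.000
    9BB      BB    9  17.211  15.239   3.000
   10BB      BB   10  16.777  15.788   3.000
   11BB      BB   11  16.302  16.302   3.000
   12BB      BB   12  15.788  16.777   3.000
   13BB      BB   13  15.239  17.211   3.000
   14BB      BB   14  14.657  17.599   3.000
   15BB      BB   15  14.046  17.941   3.000
   16BB      BB   16  13.411  18.234   3.000
   17BB      BB   17  12.754  18.476   3.000
   18BB      BB   18  12.081  18.666   3.000
   19BB      BB   19  11.394  18.803   3.000
   20BB      BB   20  10.699  18.885   3.000
   21BB      BB   21  10.000  18.913   3.000
   22BB      BB   22   9.301  18.885   3.000
   23BB      BB   23   8.606  18.803   3.000
   24BB      BB   24   7.919  18.666   3.000
   25BB      BB   25   7.246  18.476   3.000
   26BB      BB   26   6.589  18.234   3.000
   27BB      BB   27   5.954  17.941   3.000
   28BB      BB   28   5.343  17.599   3.000
   29BB      BB   29   4.761  17.211   3.000
   30BB      BB   30   4.212  16.777   3.000
   31BB      BB   31   3.698  16.302   3.000
   32BB      BB   32   3.223  15.788   3.000
   33BB      BB   33   2.789  15.239   3.000
   34BB      BB   34   2.401  14.657   3.000
   35BB      BB   35   2.059  14.046   3.000
   36BB      BB   36   1.766  13.411   3.000
   37BB      BB   37   1.524  12.754   3.000
   38BB      BB   38   1.334  12.081   3.000
   39BB      BB   39   1.197  11.394   3.000
   40BB      BB   40   1.115  10.699   3.000
   41BB      BB   41   1.087  10.000   3.000
   42BB      BB   42   1.115   9.301   3.000
   43BB      BB   43   1.197   8.606   3.000
   44BB      BB   44   1.334   7.919   3.000
   45BB      BB   45   1.524   7.246   3.000
   46BB      BB   46   1.766   6.589   3.000
   47BB      BB   47   2.059   5.954   3.000
   48BB      BB   48   2.401   5.343   3.000
   49BB      BB   49   2.789   4.761   3.000
   50BB      BB   50   3.223   4.212   3.000
   51BB      BB   51   3.698   3.698   3.000
   52BB      BB   52   4.212   3.223   3.000
   53BB      BB   53   4.761   2.789   3.000
   54BB      BB   54   5.343   2.401   3.000
   55BB      BB   55   5.954   2.059   3.000
   56BB      BB   56   6.589   1.766   3.000
   57BB      BB   57   7.246   1.524   3.000
   58BB      BB   58   7.919   1.334   3.000
   59BB      BB   59   8.606   1.197   3.000
   60BB      BB   60   9.301   1.115   3.000
   61BB      BB   61  10.000   1.087   3.000
   62BB      BB   62  10.699   1.115   3.000
   63BB      BB   63  11.394   1.197   3.000
   64BB      BB   64  12.081   1.334   3.000
   65BB      BB   65  12.754   1.524   3.000
   66BB      BB   66  13.411   1.766   3.000
   67BB      BB   67  14.046   2.059   3.000
   68BB      BB   68  14.657   2.401   3.000
   69BB      BB   69  15.239   2.789   3.000
   70BB      BB   70  15.788   3.223   3.000
   71BB      BB   71  16.302   3.698   3.000
   72BB      BB   72  16.777   4.212   3.000
   73BB      BB   73  17.211   4.761   3.000
   74BB      BB   74  17.599   5.343   3.000
   75BB      BB   75  17.941   5.954   3.000
   76BB      BB   76  18.234   6.589   3.000
   77BB      BB   77  18.476   7.246   3.000
   78BB      BB   78  18.666   7.919   3.000
   79BB      BB   79  18.803   8.606   3.000
   80BB      BB   80  18.885   9.301   3.000
   81LIN     Q0   81  18.714  12.831   3.150
   81LIN     T1   82  18.714  12.831   2.750
   81LIN     T2   83  18.714  12.831   2.350
   82LIN     Q0   84  18.742  10.284   4.700
   82LIN     T1   85  18.742  10.284   4.300
   82LIN     T2   86  18.742  10.284   3.900
   83LIN     Q0   87   5.723   7.804   4.700
   83LIN     T1   88   5.723   7.804   4.300
   83LIN     T2   89   5.723   7.804   3.900
   84LIN     Q0   90  16.609  18.115   4.700
   84LIN     T1   91  16.609  18.115   4.300
   84LIN     T2   92  16.609  18.115   3.900
   85LIN     Q0   93  12.835   8.939   4.700
   85LIN     T1   94  12.835   8.939   4.300
   85LIN     T2   95  12.835   8.939   3.900
   86LIN     Q0   96  10.382  16.720   4.700
   86LIN     T1   97  10.382  16.720   4.300
   86LIN     T2   98  10.382  16.720   3.900
   87LIN     Q0   99  14.732  14.752   4.700
   87LIN     T1  100  14.732  14.752   4.300
   87LIN     T2  101  14.732  14.752   3.900
   88LIN     Q0  102   2.693  16.221   4.700
   88LIN     T1  103   2.693  16.221   4.300
   88LIN     T2  104   2.693  16.221   3.900
   89LIN     Q0  105  13.140   7.762   1.300
   89LIN     T1  106  13.140   7.762   1.700
   89LIN     T2  107  13.140   7.762   2.100
   90LIN     Q0  108  14.101  13.703   1.300
   90LIN     T1  109  14.101  13.703   1.700
   90LIN     T2  110  14.101  13.703   2.100
   91LIN     Q0  111   9.155   0.079   1.300
   91LIN     T1  112   9.155   0.079   1.700
   91LIN     T2  113   9.155   0.079   2.100
   92LIN     Q0  114  14.382  16.658   1.300
   92LIN     T1  115  14.382  16.658   1.700
   92LIN     T2  116  14.382  16.658   2.100
   93STE     Q0  117  18.693   0.147   4.700
   93STE     T1  118  18.693   0.147   4.300
   93STE     T2  119  18.693   0.147   3.900
   94STE     Q0  120   5.109   4.153   4.700
   94STE     T1  121   5.109   4.153   4.300
   94STE     T2  122   5.109   4.153   3.900
   95STE     Q0  123   9.246  18.132   4.700
   95STE     T1  124   9.246  18.132   4.300
   95STE     T2  125   9.246  18.132   3.900
   96STE     Q0  126  18.800  12.236   4.700
   96STE     T1  127  18.800  12.236   4.300
   96STE     T2  128  18.800  12.236   3.900
   97STE     Q0  129  19.565   7.591   4.700
   97STE     T1  130  19.565   7.591   4.300
   97STE     T2  131  19.565   7.591   3.900
   98STE     Q0  132   2.350   8.715   4.700
   98STE     T1  133   2.350   8.715   4.300
   98STE     T2  134   2.350   8.715   3.900
   99STE     Q0  135   9.500   0.749   4.700
   99STE     T1  136   9.500   0.749   4.300
   99STE     T2  137   9.500   0.749   3.900
  100STE     Q0  138  11.207  19.471   4.700
  100STE     T1  139  11.207  19.471   4.300
  100STE     T2  140  11.207  19.471   3.900
  101STE     Q0  141  18.081   8.635   1.300
  101STE     T1  142  18.081   8.635   1.700
  101STE     T2  143  18.081   8.635   2.100
  102STE     Q0  144   2.774  19.152   1.300
  102STE     T1  145   2.774  19.152   1.700
  102STE     T2  146   2.774  19.152   2.100
  103STE     Q0  147  19.778  17.755   1.300
  103STE     T1  148  19.778  17.755   1.700
  103STE     T2  149  19.778  17.755   2.100
  104STE     Q0  150  18.933  12.800   1.300
  104STE     T1  151  18.933  12.800   1.700
  104STE     T2  152  18.933  12.800   2.100
  20.00000  20.00000   6.00000
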