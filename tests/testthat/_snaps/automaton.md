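# the generated transition table matches its frozen snapshot

    Code
      print(unname(tab))
    Output
            [,1] [,2] [,3] [,4] [,5] [,6] [,7] [,8] [,9] [,10] [,11] [,12] [,13]
       [1,]    1    2    3    4    5    6    7    8    9    10    11    12    13
       [2,]    1    5    5    5    5   21   25   25   25    25    21    25    25
       [3,]    5    2    5    5    5   25   22   25   25    25    25    22    25
       [4,]    5    5    3    5    5   25   25   23   25    25    25    25    23
       [5,]    5    5    5    4    5   25   25   25   24    25    25    25    25
       [6,]    5    5    5    5    5   25   25   25   25    25    25    25    25
       [7,]   21   25   25   25   25    6   10   10   10    10    21    25    25
       [8,]   25   22   25   25   25   10    7   10   10    10    25    22    25
       [9,]   25   25   23   25   25   10   10    8   10    10    25    25    23
      [10,]   25   25   25   24   25   10   10   10    9    10    25    25    25
      [11,]   25   25   25   25   25   10   10   10   10    10    25    25    25
      [12,]   21   25   25   25   25   21   25   25   25    25    11    15    15
      [13,]   25   22   25   25   25   25   22   25   25    25    15    12    15
      [14,]   25   25   23   25   25   25   25   23   25    25    15    15    13
      [15,]   25   25   25   24   25   25   25   25   24    25    15    15    15
      [16,]   25   25   25   25   25   25   25   25   25    25    15    15    15
      [17,]   21   25   25   25   25   21   25   25   25    25    21    25    25
      [18,]   25   22   25   25   25   25   22   25   25    25    25    22    25
      [19,]   25   25   23   25   25   25   25   23   25    25    25    25    23
      [20,]   25   25   25   24   25   25   25   25   24    25    25    25    25
      [21,]   25   25   25   25   25   25   25   25   25    25    25    25    25
      [22,]   21   25   25   25   25   21   25   25   25    25    21    25    25
      [23,]   25   22   25   25   25   25   22   25   25    25    25    22    25
      [24,]   25   25   23   25   25   25   25   23   25    25    25    25    23
      [25,]   25   25   25   24   25   25   25   25   24    25    25    25    25
      [26,]   25   25   25   25   25   25   25   25   25    25    25    25    25
            [,14] [,15] [,16] [,17] [,18] [,19] [,20] [,21] [,22] [,23] [,24] [,25]
       [1,]    14    15    16    17    18    19    20    21    22    23    24    25
       [2,]    25    25    21    25    25    25    25    21    25    25    25    25
       [3,]    25    25    25    22    25    25    25    25    22    25    25    25
       [4,]    25    25    25    25    23    25    25    25    25    23    25    25
       [5,]    24    25    25    25    25    24    25    25    25    25    24    25
       [6,]    25    25    25    25    25    25    25    25    25    25    25    25
       [7,]    25    25    21    25    25    25    25    21    25    25    25    25
       [8,]    25    25    25    22    25    25    25    25    22    25    25    25
       [9,]    25    25    25    25    23    25    25    25    25    23    25    25
      [10,]    24    25    25    25    25    24    25    25    25    25    24    25
      [11,]    25    25    25    25    25    25    25    25    25    25    25    25
      [12,]    15    15    21    25    25    25    25    21    25    25    25    25
      [13,]    15    15    25    22    25    25    25    25    22    25    25    25
      [14,]    15    15    25    25    23    25    25    25    25    23    25    25
      [15,]    14    15    25    25    25    24    25    25    25    25    24    25
      [16,]    15    15    25    25    25    25    25    25    25    25    25    25
      [17,]    25    25    16    20    20    20    20    21    25    25    25    25
      [18,]    25    25    20    17    20    20    20    25    22    25    25    25
      [19,]    25    25    20    20    18    20    20    25    25    23    25    25
      [20,]    24    25    20    20    20    19    20    25    25    25    24    25
      [21,]    25    25    20    20    20    20    20    25    25    25    25    25
      [22,]    25    25    21    25    25    25    25    21    25    25    25    25
      [23,]    25    25    25    22    25    25    25    25    22    25    25    25
      [24,]    25    25    25    25    23    25    25    25    25    23    25    25
      [25,]    24    25    25    25    25    24    25    25    25    25    24    25
      [26,]    25    25    25    25    25    25    25    25    25    25    25    25

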