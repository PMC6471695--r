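emdb_id,published_resolution,dnn_predicted,cnn_predicted
8221,1.6,high,high
2984,2.2,high,high
2945,2.9,high,high
6342,2.5,high,high
8218,2.3,high,high
8222,2.5,high,high
8077,1.75,high,high
8217,1.8,high,high
8219,2.5,high,high
6313,2.5,high,high
3311,6.7,medium,high
5664,7.8,high,high
6410,7.8,high,high
4047,6.0,medium,high
1674,6.0,medium,medium
5751,8.0,high,medium
3340,7.2,medium,medium
5101,8.0,low,low
3168,7.4,medium,medium
5653,7.3,high,high
7089,13.2,low,low
1601,14.1,high,high
6013,14.8,medium,medium
3368,13.0,medium,medium
2862,12.5,low,low
3098,11.0,medium,medium
7471,12.5,medium,high
1711,13.0,low,low
5169,11.0,medium,medium
1981,14.2,high,high
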