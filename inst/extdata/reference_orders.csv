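period,target_class,distance_class,n_orders,published_rate_per_week
Original configuration,eagle,far,116,11.4
Original configuration,eagle,near,12,1.2
Original configuration,eagle,within,1,0.1
IdentiFlight system update,eagle,far,47,8.0
IdentiFlight system update,eagle,near,10,1.7
IdentiFlight system update,eagle,within,1,0.2
Equipment issue,eagle,far,318,17.3
Equipment issue,eagle,near,40,2.2
Equipment issue,eagle,within,10,0.5
Equipment replacement,eagle,far,217,40.0
Equipment replacement,eagle,near,10,1.8
Equipment replacement,eagle,within,1,0.2
Neural network upgrade,eagle,far,66,8.4
Neural network upgrade,eagle,near,1,0.1
Neural network upgrade,eagle,within,0,0.0
Original configuration,non-eagle,far,235,23.2
Original configuration,non-eagle,near,74,7.3
Original configuration,non-eagle,within,22,2.2
IdentiFlight system update,non-eagle,far,87,14.9
IdentiFlight system update,non-eagle,near,66,11.3
IdentiFlight system update,non-eagle,within,18,3.1
Equipment issue,non-eagle,far,931,50.5
Equipment issue,non-eagle,near,413,22.4
Equipment issue,non-eagle,within,112,6.1
Equipment replacement,non-eagle,far,1045,192.5
Equipment replacement,non-eagle,near,240,44.2
Equipment replacement,non-eagle,within,59,10.9
Neural network upgrade,non-eagle,far,1462,186.1
Neural network upgrade,non-eagle,near,588,74.8
Neural network upgrade,non-eagle,within,87,11.1
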