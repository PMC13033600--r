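{"type":"FeatureCollection","features":[{"type":"Feature","geometry":{"type":"Polygon","coordinates":[[[4,6],[60,8],[58,56],[30,60],[6,40],[4,6]]]},"properties":{"objectType":"annotation","classification":{"name":"tissue"}}},{"type":"Feature","geometry":{"type":"Polygon","coordinates":[[[20,20],[40,22],[42,40],[24,42],[20,20]]]},"properties":{"objectType":"annotation","classification":{"name":"tumor"}}},{"type":"Feature","geometry":{"type":"Point","coordinates":[12.5,48]},"properties":{"objectType":"annotation","classification":{"name":"lymphocyte"}}},{"type":"Feature","geometry":{"type":"Point","coordinates":[50.25,14.5]},"properties":{"objectType":"annotation","classification":{"name":"lymphocyte"}}},{"type":"Feature","geometry":{"type":"Point","coordinates":[33,52]},"properties":{"objectType":"annotation","classification":{"name":"lymphocyte"}}}]}
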